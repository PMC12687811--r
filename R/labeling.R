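#' Per-sample fractional labeling from a corrected MID
#'
#' Emits one row per isotopologue shift with its corrected fraction. Rows
#' whose shift is among the tracer's expected labels for the metabolite
#' (from the pathway atlas) are tagged `expected = TRUE`. A failed
#' normalization is flagged, not dropped.
#'
#' @param corrected a corrected `mid` (from [correct_mid()]).
#' @param sample_id sample identifier.
#' @param expected_shifts integer vector of expected shifts for this
#'   metabolite under the tracer (e.g. from [monitored_isotopologues()],
#'   excluding 0); NULL tags nothing.
#' @return data.frame(sample_id, metabolite, shift, fraction, expected,
#'   flagged).
#' @export
fractional_labeling <- function(corrected, sample_id,
                                expected_shifts = NULL) {
  v <- corrected$values
  flagged <- isTRUE(corrected$flagged) || abs(sum(v) - 1) > 1e-9
  shifts <- seq_along(v) - 1L
  data.frame(
    sample_id = sample_id, metabolite = corrected$metabolite,
    shift = shifts, fraction = v,
    expected = shifts %in% setdiff(as.integer(expected_shifts %||% integer()),
                                   0L),
    flagged = flagged, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serum enrichment time course with plateau estimate
#'
#' Orders a per-metabolite labeled-fraction series by time, estimates the
#' steady-state plateau as the mean of points at or beyond
#' `plateau_start` (default 900 min: under a 20-h constant infusion the
#' 15-h and 20-h samples define the plateau), and flags steadiness when the
#' last two points differ by less than `tol` (absolute).
#'
#' @param times sampling times in minutes (>= 3 points).
#' @param fractions labeled fractions at those times.
#' @param plateau_start start of the plateau window, minutes.
#' @param tol absolute steadiness tolerance on the last two points.
#' @return list(series = ordered data.frame(time, fraction),
#'   plateau, steady).
#' @export
enrichment_timecourse <- function(times, fractions, plateau_start = 900,
                                  tol = 0.05) {
  if (length(times) < 3L) stop("insufficient series: need >= 3 timepoints")
  if (length(times) != length(fractions))
    stop("times and fractions must have equal length")
  o <- order(times)
  times <- times[o]
  fractions <- fractions[o]
  win <- times >= plateau_start
  plateau <- if (any(win)) mean(fractions[win]) else fractions[length(fractions)]
  n <- length(fractions)
  steady <- abs(fractions[n] - fractions[n - 1L]) < tol
  list(series = data.frame(time = times, fraction = fractions),
       plateau = plateau, steady = steady)
}

#' Relative pool size as summed ion intensity (TIC)
#'
#' Sums isotopologue intensities per sample and scales so that the
#' control-group mean equals 1. Without any control sample the unscaled
#' sums are returned with a warning.
#'
#' @param peaks long peak table (sample_id, metabolite, isotopologue,
#'   intensity).
#' @param metabolite metabolite to quantify.
#' @param groups named character vector or data.frame mapping
#'   `sample_id` to group; samples with group `"control"` define the
#'   reference mean.
#' @return data.frame(sample_id, group, tic, relative) with attribute
#'   `normalization` recording the reference.
#' @export
relative_pool <- function(peaks, metabolite, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$sample_id)
  px <- peaks[peaks$metabolite == metabolite, , drop = FALSE]
  if (!nrow(px)) stop("metabolite '", metabolite, "' not in peak table")
  tic <- tapply(px$intensity, px$sample_id, sum)
  out <- data.frame(sample_id = names(tic),
                    group = unname(groups[names(tic)]),
                    tic = as.numeric(tic), stringsAsFactors = FALSE)
  ctrl <- out$tic[!is.na(out$group) & out$group == "control"]
  if (length(ctrl)) {
    out$relative <- out$tic / mean(ctrl)
    attr(out, "normalization") <- "control-group mean = 1"
  } else {
    warning("no control group: returning unscaled TIC sums")
    out$relative <- out$tic
    attr(out, "normalization") <- "none (no control group)"
  }
  out
}

#' Kynurenine / tryptophan ratio per sample
#'
#' Ratio of summed ion intensities (concentration proxies) of kynurenine to
#' tryptophan in each sample. A zero tryptophan signal yields NA, flagged.
#'
#' @param peaks long peak table containing both metabolites.
#' @param kyn,trp metabolite ids.
#' @return data.frame(sample_id, kyn_tic, trp_tic, ratio, flagged).
#' @export
kyn_trp_ratio <- function(peaks, kyn = "kynurenine", trp = "tryptophan") {
  ids <- unique(peaks$sample_id)
  k <- tapply(peaks$intensity[peaks$metabolite == kyn],
              peaks$sample_id[peaks$metabolite == kyn], sum)
  t_ <- tapply(peaks$intensity[peaks$metabolite == trp],
               peaks$sample_id[peaks$metabolite == trp], sum)
  miss <- setdiff(ids, intersect(names(k), names(t_)))
  if (length(miss))
    stop("samples missing kynurenine or tryptophan: ",
         paste(miss, collapse = ", "))
  common <- intersect(names(k), names(t_))
  kv <- as.numeric(k[common])
  tv <- as.numeric(t_[common])
  ratio <- ifelse(tv > 0, kv / tv, NA_real_)
  data.frame(sample_id = common, kyn_tic = kv, trp_tic = tv,
             ratio = ratio, flagged = tv <= 0, stringsAsFactors = FALSE)
}
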