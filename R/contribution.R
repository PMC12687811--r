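#' Nicotinamide (salvage) contribution to a tissue NAD+ pool
#'
#' Percent contribution of circulating nicotinamide to a compartment's NAD+
#' pool: 100 x tissue NAD+ M+3 fraction divided by the summed serum
#' fractional labeling of nicotinamide M+3 and M+4 at the infusion plateau
#' (the labeled serum precursor pool under the ring-deuterated tracer).
#' Values above 100 are reported, not clipped: they indicate denominator
#' underestimation.
#'
#' @param nad_m3_fraction tissue NAD+ M+3 fraction (corrected).
#' @param serum_nam_m3,serum_nam_m4 serum nicotinamide fractional labeling
#'   at the plateau, recycled (M+3) and infusate (M+4) species.
#' @return percent (vectorized); NA with a warning-free flag attribute when
#'   the denominator is zero.
#' @export
nam_contribution <- function(nad_m3_fraction, serum_nam_m3, serum_nam_m4) {
  denom <- serum_nam_m3 + serum_nam_m4
  out <- ifelse(denom > 0, 100 * nad_m3_fraction / denom, NA_real_)
  attr(out, "flagged") <- denom <= 0
  out
}

#' Tryptophan (de novo) contribution to a tissue NAD+ pool
#'
#' Percent contribution of circulating tryptophan: 100 x tissue NAD+ M+6
#' fraction divided by the serum fractional labeling of tryptophan M+11 at
#' the plateau. A tissue can show a nonzero value with no local de novo
#' flux when it salvages hepatically recycled M+6 nicotinamide; the value
#' is reported as-is.
#'
#' @param nad_m6_fraction tissue NAD+ M+6 fraction (corrected).
#' @param serum_trp_m11 serum tryptophan M+11 fractional labeling at the
#'   plateau.
#' @return percent (vectorized); NA where the denominator is zero.
#' @export
trp_contribution <- function(nad_m6_fraction, serum_trp_m11) {
  out <- ifelse(serum_trp_m11 > 0, 100 * nad_m6_fraction / serum_trp_m11,
                NA_real_)
  attr(out, "flagged") <- serum_trp_m11 <= 0
  out
}

#' Assemble per-animal precursor-contribution records with group summaries
#'
#' Combines terminal tissue NAD+ fractional labeling with each animal's own
#' serum plateau denominators. The nicotinamide and tryptophan arms come
#' from separate animals infused with separate tracers; their percentages
#' are therefore reported side by side and never forced to sum to 100.
#'
#' @param tissue_labeling data.frame(animal, compartment, metabolite,
#'   shift, fraction) of corrected tissue fractions (NAD rows are used).
#' @param serum_plateau data.frame(animal, metabolite, shift, plateau) of
#'   per-animal serum plateau fractional labeling.
#' @param tracer a [tracer_spec()] identifying the arm.
#' @param group,phase labels attached to the records.
#' @return list with `records` (per-animal ContributionRecord rows) and
#'   `summary` (mean, SEM, n per compartment x precursor); single-animal
#'   summaries carry `sem = NA` and `flagged = TRUE`. Attribute
#'   `denominator` records the plateau definition.
#' @export
contribution_table <- function(tissue_labeling, serum_plateau, tracer,
                               group = NA_character_,
                               phase = NA_character_) {
  if (!nrow(tissue_labeling) || !nrow(serum_plateau)) {
    empty <- data.frame(compartment = character(), precursor = character(),
                        animal = integer(), percent = numeric(),
                        denominator_value = numeric(), group = character(),
                        phase = character(), stringsAsFactors = FALSE)
    return(list(records = empty, summary = empty))
  }
  if (tracer$element == "H") {
    precursor <- "NAM"
    num_shift <- 3L
    denom_fun <- function(sp) {
      m3 <- sp$plateau[sp$metabolite == "NAM" & sp$shift == 3L]
      m4 <- sp$plateau[sp$metabolite == "NAM" & sp$shift == 4L]
      sum(m3, m4)
    }
  } else {
    precursor <- "Trp"
    num_shift <- 6L
    denom_fun <- function(sp) {
      sum(sp$plateau[sp$metabolite == "tryptophan" & sp$shift == 11L])
    }
  }
  nad <- tissue_labeling[tissue_labeling$metabolite == "NAD" &
                           tissue_labeling$shift == num_shift, ,
                         drop = FALSE]
  recs <- NULL
  for (a in unique(nad$animal)) {
    sp <- serum_plateau[serum_plateau$animal == a, , drop = FALSE]
    denom <- denom_fun(sp)
    rows <- nad[nad$animal == a, , drop = FALSE]
    pct <- if (denom > 0) 100 * rows$fraction / denom else NA_real_
    recs <- rbind(recs, data.frame(
      compartment = rows$compartment, precursor = precursor, animal = a,
      percent = pct, denominator_value = denom, group = group,
      phase = phase, stringsAsFactors = FALSE))
  }
  agg <- split(recs, recs$compartment)
  summary <- do.call(rbind, lapply(agg, function(g) {
    n <- sum(!is.na(g$percent))
    data.frame(compartment = g$compartment[1], precursor = precursor,
               group = group, phase = phase, n_animals = n,
               mean_percent = mean(g$percent, na.rm = TRUE),
               sem = if (n > 1) stats::sd(g$percent, na.rm = TRUE) / sqrt(n)
                     else NA_real_,
               flagged = n <= 1, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  out <- list(records = recs, summary = summary)
  attr(out, "denominator") <- "per-animal serum plateau (mean of points >= 900 min)"
  out
}

#' Estimate precursor contributions from a raw peak table
#'
#' End-to-end estimator mirroring the study workflow: per-sample
#' natural-abundance correction of every measured MID, fractional labeling,
#' per-animal serum plateau denominators, and per-animal contribution
#' records for every non-serum compartment.
#'
#' @param peaks raw long peak table (e.g. from [measure()] or
#'   [read_peak_table()]).
#' @param metadata data.frame(sample_id, animal, compartment, time_min,
#'   tracer).
#' @param map the `pathway_map`.
#' @param tracer a [tracer_spec()]; defaults to the tracer named in the
#'   metadata.
#' @param plateau_start plateau window start, minutes.
#' @param abundances,purity,resolution_mode correction settings; purity
#'   defaults to the tracer's.
#' @param group,phase labels passed through to the records.
#' @return the [contribution_table()] result, plus `labeling` (all
#'   corrected fractions) and `serum_plateau`.
#' @export
estimate_contributions <- function(peaks, metadata, map = default_atlas(),
                                   tracer = NULL, plateau_start = 900,
                                   abundances = c(C = 0.0107, H = 0.000115,
                                                  N = 0.00364, O = 0.00038),
                                   purity = NULL,
                                   resolution_mode = "high",
                                   group = NA_character_,
                                   phase = NA_character_) {
  if (is.null(tracer)) {
    tn <- unique(metadata$tracer)
    if (length(tn) != 1L) stop("metadata must name exactly one tracer")
    tracer <- map$tracers[[tn]]
    if (is.null(tracer)) stop("tracer '", tn, "' not in map")
  }
  if (is.null(purity)) purity <- tracer$purity
  monitored <- monitored_isotopologues(tracer, map)
  mets <- map$metabolites
  lab <- list()
  keys <- unique(peaks[, c("sample_id", "metabolite")])
  for (i in seq_len(nrow(keys))) {
    sid <- keys$sample_id[i]
    met <- keys$metabolite[i]
    rows <- peaks[peaks$sample_id == sid & peaks$metabolite == met, ]
    k <- as.integer(sub("^M\\+", "", rows$isotopologue))
    n_el <- mets[[tracer$element]][mets$id == met]
    raw <- numeric(n_el + 1L)
    raw[k + 1L] <- rows$intensity
    model <- correction_model(
      formula = stats::setNames(
        as.numeric(mets[mets$id == met, c("C", "H", "N", "O")]),
        c("C", "H", "N", "O")),
      tracer_element = tracer$element, abundances = abundances,
      purity = purity, resolution_mode = resolution_mode)
    corr <- correct_mid(raw, model, metabolite = met)
    lab[[i]] <- fractional_labeling(corr, sid, monitored[[met]])
  }
  lab <- do.call(rbind, lab)
  lab <- merge(lab, metadata, by = "sample_id")
  serum_lab <- lab[lab$compartment == "serum", , drop = FALSE]
  # per-animal serum plateau per metabolite x shift
  sp <- list()
  for (a in unique(serum_lab$animal)) {
    sa <- serum_lab[serum_lab$animal == a, ]
    for (met in unique(sa$metabolite)) {
      for (s in unique(sa$shift[sa$metabolite == met])) {
        rows <- sa[sa$metabolite == met & sa$shift == s, ]
        tc <- enrichment_timecourse(rows$time_min, rows$fraction,
                                    plateau_start = plateau_start)
        sp[[length(sp) + 1L]] <- data.frame(
          animal = a, metabolite = met, shift = s, plateau = tc$plateau,
          steady = tc$steady, stringsAsFactors = FALSE)
      }
    }
  }
  serum_plateau <- do.call(rbind, sp)
  terminal <- max(metadata$time_min)
  tissue <- lab[lab$compartment != "serum" & lab$time_min == terminal, ,
                drop = FALSE]
  tab <- contribution_table(tissue, serum_plateau, tracer,
                            group = group, phase = phase)
  tab$labeling <- lab
  tab$serum_plateau <- serum_plateau
  tab
}
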