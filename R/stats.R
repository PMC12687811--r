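#' Two-group Mann-Whitney U test
#'
#' Two-sided rank-sum comparison: the exact null distribution is used when
#' both groups have n <= 8 and there are no ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return data.frame(method, statistic, p_value, n1, n2, exact).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact)
  )
  data.frame(method = "mann_whitney", statistic = unname(wt$statistic),
             p_value = wt$p.value, n1 = length(x), n2 = length(y),
             exact = use_exact, stringsAsFactors = FALSE)
}

#' Significance bands used throughout
#'
#' `****` p < 0.0001, `***` < 0.001, `**` < 0.01, `*` < 0.05, and the
#' trend band `§` < 0.1; otherwise `ns`.
#'
#' @param p p-values.
#' @return character vector of bands.
#' @export
significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, 0.1, Inf),
      labels = c("****", "***", "**", "*", "§", "ns"),
      right = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H, followed by Dunn z-tests on mean ranks
#' for every group pair. Pairwise p-values are reported both raw and
#' Benjamini-Hochberg adjusted, each with its significance band.
#'
#' @param groups named list of >= 3 non-empty numeric vectors.
#' @return list(omnibus = data.frame(H, df, p_value),
#'   pairwise = data.frame(group1, group2, z, p_raw, p_bh, band_raw,
#'   band_bh)).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3L) stop("need >= 3 groups")
  if (any(!lengths(groups))) stop("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(values, g)
  # Dunn: z on mean-rank differences with tie-corrected variance
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_bh <- bh_fdr(pw$p_raw)
  pw$band_raw <- significance_band(pw$p_raw)
  pw$band_bh <- significance_band(pw$p_bh)
  list(omnibus = data.frame(H = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value),
       pairwise = pw)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p p-values in [0, 1].
#' @return adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' qPCR fold change by the 2^-ddCt method
#'
#' `2^-[(Ct_target,sample - Ct_ref,sample) - (Ct_target,control -
#' Ct_ref,control)]`, the relative expression of a target gene normalized
#' to a reference gene (TBP in the study) and to the control condition.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   threshold cycles.
#' @return fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
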