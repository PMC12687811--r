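#' Weight-loss points of the disease activity index
#'
#' Bins percent weight loss (vs day 0) per the clinical rubric: 0 = no loss
#' or gain, 1 = 1-5%, 2 = 6-10%, 3 = 11-19%, 4 = 20-25%, 5 = >25%. The
#' printed bins are integer-edged; non-integer losses are rounded half-up
#' to an integer before binning, which leaves no gaps.
#'
#' @param pct_loss percent weight loss (positive = loss; negative values
#'   are gains and score 0). Vectorized.
#' @return integer points 0-5.
#' @export
weight_points <- function(pct_loss) {
  if (any(!is.finite(pct_loss))) stop("pct_loss must be finite")
  r <- floor(pct_loss + 0.5)  # round half-up
  pts <- integer(length(r))
  pts[r >= 1 & r <= 5] <- 1L
  pts[r >= 6 & r <= 10] <- 2L
  pts[r >= 11 & r <= 19] <- 3L
  pts[r >= 20 & r <= 25] <- 4L
  pts[r > 25] <- 5L
  pts
}

#' Disease activity index of one observation
#'
#' Combines the weight-loss points with the five observed ordinal
#' components (stool consistency, bleeding, posture, activity, fur, each
#' 0-5) into the total DAI (0-30, the plain sum of the six components).
#'
#' @param weight_pct_change percent change vs day 0 (negative = loss).
#' @param stool,bleeding,posture,activity,fur ordinal scores, integers 0-5.
#' @return list(weight_points, total). Vectorized over observations.
#' @export
dai <- function(weight_pct_change, stool, bleeding, posture, activity,
                fur) {
  ords <- cbind(stool, bleeding, posture, activity, fur)
  if (any(ords != floor(ords)) || any(ords < 0) || any(ords > 5))
    stop("ordinal components must be integers in [0, 5]")
  wp <- weight_points(-weight_pct_change)  # loss is a negative change
  list(weight_points = wp,
       total = as.integer(wp + rowSums(ords)))
}

#' Daily group summaries of the disease activity index
#'
#' @param obs data.frame with columns mouse_id, day, group,
#'   weight_pct_change, stool, bleeding, posture, activity, fur.
#' @return data.frame(day, group, n, mean_dai, sem); single-mouse days
#'   carry `sem = NA`.
#' @export
dai_timecourse <- function(obs) {
  if (!nrow(obs)) {
    return(data.frame(day = numeric(), group = character(), n = integer(),
                      mean_dai = numeric(), sem = numeric(),
                      stringsAsFactors = FALSE))
  }
  sc <- dai(obs$weight_pct_change, obs$stool, obs$bleeding, obs$posture,
            obs$activity, obs$fur)
  obs$total <- sc$total
  agg <- split(obs, interaction(obs$day, obs$group, drop = TRUE))
  out <- do.call(rbind, lapply(agg, function(g) {
    n <- nrow(g)
    data.frame(day = g$day[1], group = g$group[1], n = n,
               mean_dai = mean(g$total),
               sem = if (n > 1) stats::sd(g$total) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$day), ]
  rownames(out) <- NULL
  out
}
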