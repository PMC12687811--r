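#' Natural-abundance correction model
#'
#' Parameters governing how a measured mass-isotopomer distribution (MID)
#' relates to the tracer-derived one: the molecular formula, which element
#' the tracer labels, natural heavy-isotope abundances, per-position tracer
#' purity, and the resolution mode. In `"high"` mode (the default, suited to
#' Orbitrap-class resolution where isotopologues of different elements are
#' mass-resolved) only the tracer element is convolved; `"nominal"` mode
#' additionally convolves all other elements onto the nominal mass axis.
#'
#' @param formula named numeric vector of element counts, e.g.
#'   `c(C = 6, H = 6, N = 2, O = 1)` for nicotinamide.
#' @param tracer_element `"C"` or `"H"`.
#' @param abundances named vector of natural heavy-isotope fractions per
#'   element (+1 isotopes; 18O handled internally in nominal mode).
#' @param purity per-heavy-position tracer isotopic purity in (0, 1].
#' @param resolution_mode `"high"` or `"nominal"`.
#' @return object of class `correction_model`.
#' @export
correction_model <- function(formula, tracer_element = "C",
                             abundances = c(C = 0.0107, H = 0.000115,
                                            N = 0.00364, O = 0.00038),
                             purity = 0.99,
                             resolution_mode = c("high", "nominal")) {
  resolution_mode <- match.arg(resolution_mode)
  tracer_element <- match.arg(tracer_element, c("C", "H"))
  if (!tracer_element %in% names(formula))
    stop("formula must contain the tracer element")
  if (any(abundances < 0 | abundances >= 0.5))
    stop("abundances must lie in [0, 0.5)")
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  structure(
    list(formula = formula, tracer_element = tracer_element,
         abundances = abundances, purity = purity,
         resolution_mode = resolution_mode),
    class = "correction_model"
  )
}

#' Mass-isotopomer distribution vector
#'
#' @param metabolite metabolite id.
#' @param values numeric vector over M+0..M+n (intensities or fractions).
#' @param kind `"raw"` or `"corrected"`.
#' @param flagged quality flag.
#' @param residual relative fit residual from correction (if any).
#' @return object of class `mid`.
#' @export
mid_vector <- function(metabolite, values, kind = c("raw", "corrected"),
                       flagged = FALSE, residual = NA_real_) {
  kind <- match.arg(kind)
  if (any(values < 0)) stop("MID values must be non-negative")
  structure(list(metabolite = metabolite, values = as.numeric(values),
                 kind = kind, flagged = flagged, residual = residual),
            class = "mid")
}

# distribution of heavy-atom count for m positions each heavy with prob p
binom_pattern <- function(m, p) {
  if (m == 0L) return(1)
  stats::dbinom(0:m, m, p)
}

# convolve two probability vectors (supports from 0); direct sum, so the
# result is exactly non-negative
conv0 <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Build the natural-abundance / purity correction matrix
#'
#' Column `j` holds the expected raw isotopologue distribution of a species
#' that is truly M+j: the `j` intended-heavy positions each carry the heavy
#' isotope with probability `purity`, and the remaining tracer-element
#' positions each pick up a natural heavy isotope with its natural
#' abundance. In nominal mode the other elements' natural isotopes
#' (including 18O at +2) are convolved on top, truncated to the 0..n axis.
#'
#' @param model a [correction_model()].
#' @return (n+1) x (n+1) matrix over shifts 0..n where n is the
#'   tracer-element count; a 1x1 identity when the formula has no
#'   tracer-element atoms.
#' @export
build_correction_matrix <- function(model) {
  n <- as.integer(model$formula[[model$tracer_element]])
  if (n == 0L) return(matrix(1, 1, 1))
  p_nat <- model$abundances[[model$tracer_element]]
  other <- 1
  if (model$resolution_mode == "nominal") {
    for (el in names(model$formula)) {
      if (el == model$tracer_element) next
      cnt <- as.integer(model$formula[[el]])
      if (cnt == 0L) next
      a <- if (el %in% names(model$abundances)) model$abundances[[el]] else 0
      other <- conv0(other, binom_pattern(cnt, a))
      if (el == "O") {
        # 18O is a +2 isotope: convolve its binomial on a stride-2 axis
        p18 <- 0.00205
        b <- binom_pattern(cnt, p18)
        b2 <- numeric(2L * cnt + 1L)
        b2[seq(1L, by = 2L, length.out = cnt + 1L)] <- b
        other <- conv0(other, b2)
      }
    }
  }
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    col <- conv0(binom_pattern(j, model$purity),
                 binom_pattern(n - j, p_nat))
    col <- conv0(col, other)
    M[, j + 1L] <- col[seq_len(n + 1L)]
  }
  M
}

#' Forward-convolve a true MID into its expected raw measurement
#'
#' Brute-force application of the correction matrix: the expected
#' natural-abundance- and purity-blurred distribution the instrument would
#' record for a given tracer-derived MID. Serves as the independent oracle
#' for [correct_mid()] and as the forward model of the synthetic-data
#' generator.
#'
#' @param true_mid numeric vector or `mid` over M+0..M+n.
#' @param model a [correction_model()].
#' @return numeric vector (same length) of expected raw values.
#' @export
forward_convolve <- function(true_mid, model) {
  v <- if (inherits(true_mid, "mid")) true_mid$values else as.numeric(true_mid)
  M <- build_correction_matrix(model)
  if (length(v) != nrow(M))
    stop("MID length ", length(v), " does not match matrix size ", nrow(M))
  as.numeric(M %*% v)
}

#' Correct a raw MID for natural abundance and tracer purity
#'
#' Solves `M x = raw` for `x >= 0` by non-negative least squares
#' (guaranteeing non-negative corrected fractions rather than clamping a
#' direct inversion), then renormalizes to sum 1. The relative fit residual
#' is recorded and the result flagged when it exceeds 1e-3.
#'
#' @param raw numeric vector or `mid` of raw intensities/fractions over
#'   M+0..M+n.
#' @param model a [correction_model()].
#' @param metabolite metabolite id for the returned record.
#' @return a `mid` of kind `"corrected"` with fractions summing to 1.
#' @export
correct_mid <- function(raw, model, metabolite = NA_character_) {
  v <- if (inherits(raw, "mid")) raw$values else as.numeric(raw)
  if (inherits(raw, "mid") && is.na(metabolite)) metabolite <- raw$metabolite
  if (all(v == 0)) stop("empty measurement: all-zero raw vector")
  M <- build_correction_matrix(model)
  if (length(v) != nrow(M))
    stop("MID length ", length(v), " does not match matrix size ", nrow(M))
  if (nrow(M) == 1L) {
    return(mid_vector(metabolite, 1, "corrected", FALSE, 0))
  }
  # corrected fractions are invariant to overall intensity scaling, and
  # the NNLS tolerance is absolute: solve on the sum-normalized vector
  v <- v / sum(v)
  fit <- pracma::lsqnonneg(M, v)
  x <- fit$x
  resid <- sqrt(sum((M %*% x - v)^2)) / sqrt(sum(v^2))
  if (sum(x) <= 0) stop("correction produced an all-zero result")
  x <- x / sum(x)
  mid_vector(metabolite, x, "corrected",
             flagged = resid > 1e-3, residual = resid)
}
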