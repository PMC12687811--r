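test_that("correction matrix columns follow the binomial forward model", {
  # C2 molecule, natural 13C only: column 0 is the binomial expansion
  p <- 0.0107
  m <- correction_model(c(C = 2, H = 4, N = 0, O = 0), "C", purity = 1)
  M <- build_correction_matrix(m)
  expect_equal(M[, 1], c((1 - p)^2, 2 * p * (1 - p), p^2), tolerance = 1e-12)
  expect_true(all(abs(colSums(M) - 1) < 1e-12))

  # positional-purity model: fully labeled species retains all n heavy
  # atoms with probability purity^n
  m99 <- correction_model(c(C = 6, H = 6, N = 2, O = 1), "C", purity = 0.99)
  M99 <- build_correction_matrix(m99)
  expect_equal(M99[7, 7], 0.99^6 * (1 - 0.0107)^0, tolerance = 1e-12)

  # no tracer-element atoms: identity
  m0 <- correction_model(c(C = 0, H = 2, N = 0, O = 1), "C")
  expect_equal(build_correction_matrix(m0), matrix(1, 1, 1))
})

test_that("forward convolution matches hand-computed binomial terms", {
  p <- 0.0107
  m <- correction_model(c(C = 6, H = 6, N = 2, O = 1), "C", purity = 1)
  raw <- forward_convolve(c(1, rep(0, 6)), m)
  expect_equal(raw[2], 6 * p * (1 - p)^5, tolerance = 1e-12)
  # zero abundances leave a pure M+0 untouched
  m0 <- correction_model(c(C = 6, H = 6, N = 2, O = 1), "C",
                         abundances = c(C = 0, H = 0, N = 0, O = 0),
                         purity = 1)
  expect_equal(forward_convolve(c(1, rep(0, 6)), m0), c(1, rep(0, 6)))
})

test_that("correct_mid inverts the forward model (round-trip oracle)", {
  set.seed(20240701)
  worst <- 0
  for (i in 1:200) {
    nC <- sample(1:12, 1)
    model <- correction_model(
      c(C = nC, H = sample(1:12, 1), N = sample(0:3, 1), O = sample(0:4, 1)),
      "C", purity = stats::runif(1, 0.95, 1))
    true <- stats::runif(nC + 1)
    true <- true / sum(true)
    rec <- correct_mid(forward_convolve(true, model), model)
    worst <- max(worst, max(abs(rec$values - true)))
    expect_false(rec$flagged)
  }
  expect_lt(worst, 1e-8)
})

test_that("correction recovers pure M+0 from its natural-abundance pattern", {
  model <- correction_model(c(C = 11, H = 12, N = 2, O = 2), "C")
  raw <- forward_convolve(c(1, rep(0, 11)), model)
  rec <- correct_mid(raw, model)
  expect_equal(rec$values, c(1, rep(0, 11)), tolerance = 1e-8)
})

test_that("corrected fractions are invariant to intensity scaling", {
  model <- correction_model(c(C = 6, H = 6, N = 2, O = 1), "C")
  raw <- forward_convolve(c(0.7, 0.1, 0, 0.05, 0, 0, 0.15), model)
  a <- correct_mid(raw, model)$values
  b <- correct_mid(raw * 3.7e6, model)$values
  expect_equal(a, b, tolerance = 1e-10)
  expect_equal(sum(a), 1, tolerance = 1e-12)
})

test_that("deuterium corrections are smaller than carbon for one formula", {
  f <- c(C = 6, H = 6, N = 2, O = 1)
  mC <- correction_model(f, "C", purity = 1)
  mH <- correction_model(f, "H", purity = 1)
  rawC <- forward_convolve(c(1, rep(0, 6)), mC)
  rawH <- forward_convolve(c(1, rep(0, 6)), mH)
  # blur away from M+0 is orders of magnitude smaller for 2H
  expect_lt(1 - rawH[1], (1 - rawC[1]) / 10)
})

test_that("degenerate and invalid inputs error as specified", {
  model <- correction_model(c(C = 3, H = 4, N = 0, O = 0), "C")
  expect_error(correct_mid(c(0, 0, 0, 0), model), "empty measurement")
  expect_error(correction_model(c(H = 2, N = 1), "C"),
               "must contain the tracer element")
  expect_error(correction_model(c(C = 2, H = 1), "C", purity = 0),
               "purity")
  expect_error(correction_model(c(C = 2, H = 1), "C",
                                abundances = c(C = 0.6, H = 0)),
               "abundances")
})

test_that("identity correction under zero abundances and full purity", {
  model <- correction_model(c(C = 4, H = 4, N = 0, O = 0), "C",
                            abundances = c(C = 0, H = 0, N = 0, O = 0),
                            purity = 1)
  raw <- c(2, 1, 0, 1, 0)
  expect_equal(correct_mid(raw, model)$values, raw / sum(raw),
               tolerance = 1e-12)
})
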