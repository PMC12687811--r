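test_that("infusion arithmetic reproduces the study's delivery rates", {
  expect_equal(infusion_rate(50, 0.5, 20), 1.25)
  expect_equal(infusion_rate(4, 0.5, 20), 0.1)
  expect_equal(infusion_rate(1, 1, 1), 1)
  expect_error(infusion_rate(0, 0.5, 20), "invalid parameter")
  expect_error(infusion_rate(50, -1, 20), "invalid parameter")
})

test_that("default models are balanced and encode the flare directions", {
  map <- default_atlas()
  cfgs <- list()
  for (sc in c("control", "early_flare", "active_flare")) {
    for (tr in list(tracer_nam_d4(), tracer_trp13c())) {
      cfg <- build_default_model(sc, tr, seed = 1)
      expect_length(validate_sim_config(cfg, map), 0)
      cfgs[[paste(sc, tr$element)]] <- cfg
    }
  }
  pool <- function(cfg, comp, met) {
    cfg$pools$size[cfg$pools$compartment == comp &
                     cfg$pools$metabolite == met]
  }
  rate <- function(cfg, from_met, to_met, comp) {
    f <- cfg$fluxes
    sum(f$rate[f$type == "convert" & !is.na(f$from_comp) &
                 f$from_comp == comp & f$from_met == from_met &
                 f$to_met == to_met])
  }
  # colonic NAD pool shrinks in active flare
  expect_lt(pool(cfgs[["active_flare H"]], "colon", "NAD"),
            pool(cfgs[["control H"]], "colon", "NAD"))
  # colonic salvage flux and NAD consumption rise
  expect_gt(rate(cfgs[["active_flare H"]], "NAM", "NMN", "colon"),
            rate(cfgs[["control H"]], "NAM", "NMN", "colon"))
  # hepatic de novo entry rises in the tryptophan arm
  expect_gt(rate(cfgs[["active_flare C"]], "tryptophan",
                 "N-formylkynurenine", "liver"),
            rate(cfgs[["control C"]], "tryptophan",
                 "N-formylkynurenine", "liver"))
  expect_error(build_default_model("remission"), "arg")
})

test_that("simulator matches the one-pool closed form", {
  map <- default_atlas()
  f_in <- 0.1; src <- 0.4; Q <- 2
  cfg <- one_pool_config(f_in, src, Q)
  sim <- simulate_infusion(cfg, map)
  tr <- sim$trajectories
  lab <- tr[tr$shift == 4L, ]
  k <- (f_in + src) / Q
  f <- f_in / (f_in + src)
  expect_equal(lab$fraction, f * (1 - exp(-k * lab$time)),
               tolerance = 1e-6)
})

test_that("zero infusion leaves every pool unlabeled", {
  map <- default_atlas()
  cfg <- one_pool_config(f_in = 0, src = 0.5)
  sim <- simulate_infusion(cfg, map)
  tr <- sim$trajectories
  expect_true(all(tr$fraction[tr$shift == 0L] == 1))
  expect_true(all(tr$fraction[tr$shift != 0L] == 0))
})

test_that("downstream pools reach the upstream steady-state enrichment", {
  map <- default_atlas()
  sim <- simulate_infusion(two_pool_config(), map)
  tr <- sim$trajectories
  at_end <- tr[tr$time == 1200 & tr$shift == 4L, ]
  up <- at_end$fraction[at_end$compartment == "serum"]
  down <- at_end$fraction[at_end$compartment == "colon"]
  expect_equal(down, up, tolerance = 1e-4)
})

test_that("fractions sum to one and rise monotonically under infusion", {
  map <- default_atlas()
  cfg <- build_default_model("control", tracer_nam_d4(), seed = 3)
  sim <- simulate_infusion(cfg, map)
  tr <- sim$trajectories
  sums <- stats::aggregate(fraction ~ time + compartment + metabolite,
                           tr, sum)
  expect_true(all(abs(sums$fraction - 1) < 1e-8))
  expect_true(all(tr$fraction >= -1e-10 & tr$fraction <= 1 + 1e-10))
  # labeled fractions non-decreasing from a previously unlabeled start
  lab <- tr[tr$shift != 0L, ]
  key <- paste(lab$compartment, lab$metabolite, lab$shift)
  for (k in unique(key)) {
    series <- lab[key == k, ]
    series <- series[order(series$time), ]
    expect_true(all(diff(series$fraction) > -1e-9))
  }
})

test_that("unbalanced configs are refused with the failing pool named", {
  map <- default_atlas()
  cfg <- one_pool_config()
  cfg$fluxes$rate[cfg$fluxes$type == "sink"] <- 0.1
  expect_match(validate_sim_config(cfg, map), "steady state", all = FALSE)
  expect_error(simulate_infusion(cfg, map), "unbalanced")
})

test_that("measurement forward model is exact when degenerate", {
  map <- default_atlas()
  cfg <- one_pool_config(seed = 5)
  sim <- simulate_infusion(cfg, map)
  sim$tracer$purity <- 1
  obs <- measure(sim, map, noise_cv = 0,
                 abundances = c(C = 0, H = 0, N = 0, O = 0))
  tr <- sim$trajectories
  for (tp in c(0, 60, 1200)) {
    rows <- obs$peaks[grepl(sprintf("t%04d$", tp), obs$peaks$sample_id), ]
    frac <- rows$intensity / sum(rows$intensity)
    truth <- numeric(7)
    tt <- tr[tr$time == tp, ]
    truth[tt$shift + 1] <- tt$fraction
    expect_equal(frac, truth, tolerance = 1e-9)
  }
})

test_that("measurement is byte-identical under a fixed seed", {
  map <- default_atlas()
  cfg <- one_pool_config(seed = 9)
  cfg$noise_cv <- 0.1
  sim <- simulate_infusion(cfg, map)
  a <- measure(sim, map, n_reps = 3)
  b <- measure(sim, map, n_reps = 3)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$metadata, b$metadata)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  map <- default_atlas()
  cfg <- one_pool_config(seed = 13)
  cfg$sample_times <- c(0, 900, 1200)
  sim <- simulate_infusion(cfg, map)
  obs <- measure(sim, map, noise_cv = 0.1, n_reps = 50)
  m0 <- obs$peaks[obs$peaks$isotopologue == "M+0" &
                    grepl("t1200$", obs$peaks$sample_id), ]
  cv <- stats::sd(m0$intensity) / mean(m0$intensity)
  expect_gt(cv, 0.07)
  expect_lt(cv, 0.13)
})
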