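test_that("contribution formulas are exact on degenerate inputs", {
  expect_equal(as.numeric(nam_contribution(0, 0.2, 0.3)), 0)
  expect_equal(as.numeric(nam_contribution(0.5, 0.2, 0.3)), 100)
  expect_equal(as.numeric(trp_contribution(0, 0.4)), 0)
  expect_equal(as.numeric(trp_contribution(0.4, 0.4)), 100)

  # zero denominators are undefined and flagged, not clipped
  z <- nam_contribution(0.1, 0, 0)
  expect_true(is.na(as.numeric(z)))
  expect_true(attr(z, "flagged"))
  z2 <- trp_contribution(0.1, 0)
  expect_true(is.na(as.numeric(z2)))

  # homogeneity: common scaling of numerator and denominator cancels
  expect_equal(as.numeric(nam_contribution(0.02, 0.01, 0.03)),
               as.numeric(nam_contribution(0.02 * 1.7, 0.01 * 1.7,
                                           0.03 * 1.7)))
  # >100% is reported as-is under denominator underestimation
  expect_gt(as.numeric(trp_contribution(0.5, 0.4)), 100)
})

test_that("noise-free single-source simulations recover truth within 5%", {
  # pure salvage sourcing: a colon NAD pool fed only by serum-equilibrated
  # NAM reads ~100% of its configured (100%) salvage share
  map <- default_atlas()
  cfg <- sim_config(
    compartments = c("serum", "colon"),
    pools = rbind(
      data.frame(compartment = "serum", metabolite = "NAM", size = 0.5),
      data.frame(compartment = "colon", metabolite = "NAM", size = 2),
      data.frame(compartment = "colon", metabolite = "NMN", size = 0.2),
      data.frame(compartment = "colon", metabolite = "NAD", size = 5)
    ),
    fluxes = rbind(
      nadflux:::flux("transport", "serum", "NAM", "colon", "NAM", 5),
      nadflux:::flux("transport", "colon", "NAM", "serum", "NAM", 4.5),
      nadflux:::flux("convert", "colon", "NAM", "colon", "NMN", 0.5,
                     "salvage"),
      nadflux:::flux("convert", "colon", "NMN", "colon", "NAD", 0.5,
                     "salvage"),
      nadflux:::flux("sink", "colon", "NAD", NA, NA, 0.5),
      nadflux:::flux("source", NA, NA, "serum", "NAM", 0.4)
    ),
    infusion = list(tracer = "nam_d4", rate = 0.1, duration = 2400,
                    compartment = "serum", metabolite = "NAM"),
    sample_times = c(0, 60, 300, 900, 1500, 2400),
    noise_cv = 0, seed = 2
  )
  sim <- simulate_infusion(cfg, map)
  expect_equal(
    sim$ground_truth_contributions$percent[
      sim$ground_truth_contributions$precursor == "NAM"], 100)
  tr <- sim$trajectories
  end <- tr[tr$time == 2400, ]
  nad3 <- end$fraction[end$compartment == "colon" & end$metabolite == "NAD" &
                         end$shift == 3]
  serum_frac <- function(s) {
    v <- end$fraction[end$compartment == "serum" & end$shift == s]
    if (length(v)) v else 0
  }
  est <- as.numeric(nam_contribution(nad3, serum_frac(3), serum_frac(4)))
  expect_gt(est, 95)
  expect_lt(est, 105)
})

test_that("recycled hepatic NAM makes colonic 'Trp contribution' nonzero
           without local de novo flux", {
  map <- default_atlas()
  cfg <- build_default_model("active_flare", tracer_trp13c(), seed = 17,
                             noise_cv = 0)
  sim <- simulate_infusion(cfg, map)
  gt <- sim$ground_truth_contributions
  # configured truth: no colonic de novo synthesis
  expect_equal(gt$percent[gt$compartment == "colon" &
                            gt$precursor == "Trp"], 0)
  tr <- sim$trajectories
  end <- tr[tr$time == 1200, ]
  nad6 <- end$fraction[end$compartment == "colon" &
                         end$metabolite == "NAD" & end$shift == 6]
  trp11 <- end$fraction[end$compartment == "serum" &
                          end$metabolite == "tryptophan" & end$shift == 11]
  est <- as.numeric(trp_contribution(nad6, trp11))
  expect_gt(est, 0)
  # liver, the de novo organ, reads a much larger value
  nad6_liver <- end$fraction[end$compartment == "liver" &
                               end$metabolite == "NAD" & end$shift == 6]
  expect_gt(as.numeric(trp_contribution(nad6_liver, trp11)), est)
})

test_that("contribution_table assembles per-animal records and summaries", {
  tissue <- data.frame(
    animal = rep(1:3, each = 2),
    compartment = rep(c("liver", "colon"), 3),
    metabolite = "NAD", shift = 3L,
    fraction = c(0.030, 0.020, 0.032, 0.022, 0.028, 0.018)
  )
  serum <- do.call(rbind, lapply(1:3, function(a) {
    data.frame(animal = a, metabolite = "NAM", shift = c(3L, 4L),
               plateau = c(0.013, 0.032))
  }))
  tab <- contribution_table(tissue, serum, tracer_nam_d4(),
                            group = "DSS", phase = "active_flare")
  expect_equal(nrow(tab$records), 6)
  expect_equal(tab$records$percent[1], 100 * 0.030 / 0.045)
  s <- tab$summary
  expect_equal(s$n_animals, c(3, 3))
  expect_false(any(s$flagged))
  expect_equal(s$mean_percent[s$compartment == "colon"],
               mean(100 * c(0.020, 0.022, 0.018) / 0.045))

  # single animal: SEM undefined, flagged
  tab1 <- contribution_table(tissue[tissue$animal == 1, ],
                             serum[serum$animal == 1, ], tracer_nam_d4())
  expect_true(all(is.na(tab1$summary$sem)))
  expect_true(all(tab1$summary$flagged))

  # empty input: empty table
  tab0 <- contribution_table(tissue[0, ], serum[0, ], tracer_nam_d4())
  expect_equal(nrow(tab0$records), 0)
})
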