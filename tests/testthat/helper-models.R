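# Shared fixtures built in code.

# Minimal one-pool turnover model: constant labeled infusion f_in plus
# unlabeled source into a single well-mixed nicotinamide pool with a
# balancing sink. Closed form for the labeled fraction:
#   L(t) = f * (1 - exp(-k t)),  f = f_in / (f_in + src),
#   k = (f_in + src) / Q
one_pool_config <- function(f_in = 0.1, src = 0.4, Q = 2, seed = 1,
                            sample_times = c(0, 5, 10, 20, 60, 120, 900,
                                             1200)) {
  sim_config(
    compartments = "serum",
    pools = data.frame(compartment = "serum", metabolite = "NAM",
                       size = Q),
    fluxes = rbind(
      nadflux:::flux("source", NA, NA, "serum", "NAM", src),
      nadflux:::flux("sink", "serum", "NAM", NA, NA, f_in + src)
    ),
    infusion = list(tracer = "nam_d4", rate = f_in, duration = 1200,
                    compartment = "serum", metabolite = "NAM"),
    sample_times = sample_times, noise_cv = 0, seed = seed
  )
}

# Two-pool chain: labeled serum pool feeding a downstream colon pool.
two_pool_config <- function(seed = 1) {
  sim_config(
    compartments = c("serum", "colon"),
    pools = rbind(
      data.frame(compartment = "serum", metabolite = "NAM", size = 0.5),
      data.frame(compartment = "colon", metabolite = "NAM", size = 2)
    ),
    fluxes = rbind(
      nadflux:::flux("transport", "serum", "NAM", "colon", "NAM", 1.0),
      nadflux:::flux("sink", "colon", "NAM", NA, NA, 1.0),
      nadflux:::flux("source", NA, NA, "serum", "NAM", 0.9),
      nadflux:::flux("sink", "serum", "NAM", NA, NA, 1.0)
    ),
    infusion = list(tracer = "nam_d4", rate = 1.1, duration = 1200,
                    compartment = "serum", metabolite = "NAM"),
    sample_times = c(0, 15, 30, 60, 120, 360, 900, 1200),
    noise_cv = 0, seed = seed
  )
}

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments (independent oracle for the rank-based implementation).
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  lo <- mean(all_u <= obs)
  hi <- mean(all_u >= obs)
  min(1, 2 * min(lo, hi))
}
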