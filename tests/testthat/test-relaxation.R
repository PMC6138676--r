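test_that("exponential fits recover exact and noiseless rates", {
  # closed form: half-life 0.5 s
  s <- decay_series(428, "R1", c(0, 0.25, 0.5, 1),
                    100 * exp(-log(2) / 0.5 * c(0, 0.25, 0.5, 1)))
  f <- fit_decay(s, mc_draws = 0)
  expect_equal(f$rate, log(2) / 0.5, tolerance = 1e-9)
  expect_equal(f$amplitude, 100, tolerance = 1e-9)

  # noiseless series at the default R1 schedule: machine-precision round trip
  for (rate in c(0.5, 1.682, 5)) {
    f <- fit_decay(exact_decay(rate), mc_draws = 0)
    expect_lt(abs(f$rate - rate) / rate, 1e-9)
  }
  f2 <- fit_decay(exact_decay(20.09, delays = default_r2_delays(),
                              experiment = "R2"), mc_draws = 0)
  expect_lt(abs(f2$rate - 20.09) / 20.09, 1e-9)
})

test_that("fit is invariant to uniform intensity rescaling", {
  set.seed(7)
  d <- default_r1_delays()
  y <- 100 * exp(-1.5 * d) + rnorm(length(d), 0, 1)
  f1 <- fit_decay(decay_series(430, "R1", d, y), mc_draws = 0)
  f2 <- fit_decay(decay_series(430, "R1", d, 37.5 * y), mc_draws = 0)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-8)
  expect_equal(37.5 * f1$amplitude, f2$amplitude, tolerance = 1e-8)
})

test_that("series validation rejects bad inputs", {
  expect_error(decay_series(428, "R1", c(0, 0.1, 0.2), c(3, 2, 1)),
               ">= 4")
  expect_error(decay_series(428, "R1", c(0, 0.2, 0.1, 0.3), c(4, 3, 2, 1)))
  expect_error(decay_series(428, "R3", 1:4 / 10, 4:1))
})

test_that("Monte-Carlo rate errors track the repeated-refit SD", {
  d <- default_r1_delays()
  rate <- 1.682; i0 <- 100; noise <- 2  # 2% of I0
  s <- decay_series(431, "R1", d, i0 * exp(-rate * d), noise_rms = noise)
  sig_mc <- mc_errors(s, n_draws = 500, seed = 11)

  # oracle: SD of rates over independent noisy realizations of the truth
  set.seed(2024)
  refits <- replicate(1000, {
    y <- i0 * exp(-rate * d) + rnorm(length(d), 0, noise)
    fit_decay(decay_series(431, "R1", d, y), mc_draws = 0)$rate
  })
  expect_lt(abs(sig_mc - sd(refits)) / sd(refits), 0.20)

  # linear regime: doubling the noise ~doubles sigma
  s2 <- decay_series(431, "R1", d, i0 * exp(-rate * d), noise_rms = 2 * noise)
  sig2 <- mc_errors(s2, n_draws = 1000, seed = 12)
  sig1 <- mc_errors(s, n_draws = 1000, seed = 12)
  expect_lt(abs(sig2 / sig1 - 2) / 2, 0.15)

  expect_identical(mc_errors(s, 500, seed = 3), mc_errors(s, 500, seed = 3))
  expect_equal(mc_errors(exact_decay(1.5), n_draws = 500), 0)
  expect_error(mc_errors(s, n_draws = 50), ">= 100")
})

test_that("NOE ratio and error propagation follow the intensity formulas", {
  expect_equal(compute_noe(noe_pair(440, 0.793 * 250, 250))$noe, 0.793)
  expect_equal(compute_noe(noe_pair(440, 123, 123))$noe, 1.0)
  n <- compute_noe(noe_pair(440, 79.3, 100, noise_rms = 1))
  expect_equal(n$sigma_noe, 0.793 * sqrt((1 / 79.3)^2 + (1 / 100)^2),
               tolerance = 1e-12)
  expect_equal(n$sigma_noe, 0.01276, tolerance = 1e-3)
  expect_error(noe_pair(440, 50, 0))
})

test_that("record summaries use mean-of-ratios and flag single observations", {
  one <- data.frame(residue = 1, R1 = 2, R2 = 20, NOE = NA)
  s1 <- summarize_records(one)
  expect_equal(s1["R2_R1", "mean"], 10)
  expect_equal(s1["R2_R1", "sd"], 0)
  expect_false(s1["R2_R1", "sd_defined"])

  two <- data.frame(residue = 1:2, R1 = c(2, 1), R2 = c(20, 15))
  # mean of ratios (12.5), not ratio of means (35/3)
  expect_equal(summarize_records(two)["R2_R1", "mean"], 12.5)

  # ratio only where both rates present
  mixed <- data.frame(residue = 1:3, R1 = c(2, 1, NA), R2 = c(20, NA, 30))
  expect_equal(summarize_records(mixed)["R2_R1", "n"], 1L)
  expect_error(summarize_records(data.frame()))
})

test_that("wild-type-like fixture reproduces its generating summary stats", {
  # profile means chosen at the wild-type values; noiseless generation must
  # return exactly the generating per-residue rates, hence their summary
  prof <- ground_truth_profile()
  sim <- make_decay_series(prof, noise_rms = 0, seed = 5)
  rec <- fit_relaxation(sim$decays, sim$noe, mc_draws = 0)
  expect_equal(rec$R1, prof$true_R1, tolerance = 1e-9)
  expect_equal(rec$R2, prof$true_R2, tolerance = 1e-9)
  expect_equal(rec$NOE, prof$true_NOE, tolerance = 1e-12)
  s <- summarize_records(rec)
  expect_equal(s["R2_R1", "mean"], mean(prof$true_R2 / prof$true_R1),
               tolerance = 1e-9)
})

test_that("rates are recovered within 3 sigma for >= 95% of residues at 2% noise", {
  prof <- ground_truth_profile(residues = 428:457)
  sim <- make_decay_series(prof, noise_rms = 0.02, seed = 21)
  rec <- fit_relaxation(sim$decays, sim$noe, mc_draws = 200, seed = 31)
  truth <- data.frame(residue = prof$residues, R1 = prof$true_R1,
                      R2 = prof$true_R2)
  for (comp in c("R1", "R2")) {
    err <- abs(rec[[comp]] - truth[[comp]][match(rec$residue, truth$residue)])
    ok <- err <= 3 * rec[[paste0(comp, "_err")]]
    expect_gte(mean(ok, na.rm = TRUE), 0.95)
  }
})

test_that("all-negative intensities fall back to grid initialization", {
  d <- default_r1_delays()
  # tiny decaying signal buried below zero baseline offset is hopeless, but
  # a sign-flipped amplitude must still converge via the grid seed
  y <- -100 * exp(-1.5 * d)
  f <- igdyn:::.fit_exp(d, y)
  expect_true(f$converged)
  expect_equal(f$rate, 1.5, tolerance = 1e-6)
})
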