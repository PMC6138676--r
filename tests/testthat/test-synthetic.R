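test_that("generators are bit-identical under a fixed seed", {
  prof <- ground_truth_profile(residues = 428:439)
  a <- make_decay_series(prof, noise_rms = 0.03, seed = 7)
  b <- make_decay_series(prof, noise_rms = 0.03, seed = 7)
  expect_identical(a, b)
  expect_identical(make_shift_tables(seed = 7), make_shift_tables(seed = 7))
  m <- two_state_model(61.9, 110.1)
  expect_identical(make_thermogram(m, noise_sd = 0.1, seed = 7),
                   make_thermogram(m, noise_sd = 0.1, seed = 7))
  ref <- rand_points(12, 1)
  sp <- ensemble_spec(ref, jitter_sd = 0.02, n_frames = 5, seed = 7)
  expect_identical(make_ensemble(sp), make_ensemble(sp))
})

test_that("noiseless decays are exactly log-linear with the true slope", {
  prof <- ground_truth_profile(residues = 428:433, flexible = list())
  sim <- make_decay_series(prof, noise_rms = 0, i0 = 100, seed = 1)
  r1 <- Filter(function(d) d$experiment == "R1", sim$decays)
  for (d in r1) {
    slope <- coef(lm(log(d$intensities) ~ d$delays))[[2]]
    expect_equal(slope, -1.682, tolerance = 1e-12)
  }
  # NOE pairs satisfy I_sat = NOE * I_ref exactly before noise
  for (p in sim$noe)
    expect_equal(p$intensity_sat / p$intensity_ref, 0.793,
                 tolerance = 1e-12)
})

test_that("missing residues are omitted from every generated series", {
  prof <- ground_truth_profile(residues = 428:437, missing = c(430, 435))
  sim <- make_decay_series(prof, noise_rms = 0, seed = 1)
  res <- unique(vapply(sim$decays, function(d) d$residue, integer(1)))
  expect_false(any(c(430, 435) %in% res))
  expect_length(sim$noe, 8)
})

test_that("generated noise magnitude matches the requested SD", {
  prof <- ground_truth_profile()  # 125 residues x 16 decay points >= 1e4 draws
  i0 <- 100; frac <- 0.02
  sim <- make_decay_series(prof, noise_rms = frac, i0 = i0, seed = 3)
  # residual = intensity - i0 exp(-true rate * delay), pooled over series
  resid <- unlist(lapply(sim$decays, function(d) {
    i <- match(d$residue, prof$residues)
    rate <- if (d$experiment == "R1") prof$true_R1[i] else prof$true_R2[i]
    d$intensities - i0 * exp(-rate * d$delays)
  }))
  expect_gte(length(resid), 1e4 / 10)
  expect_lt(abs(sd(resid) - frac * i0) / (frac * i0), 0.05)
})

test_that("shift-table generator plants the requested amide perturbation", {
  # zero noise, zero amplitude: identical tables, zero CSP
  st0 <- make_shift_tables(50, c(440, 445), cluster_amplitude = 0,
                           baseline_sd = 0, seed = 2)
  expect_equal(st0$a, st0$b)
  expect_true(all(csp(st0$a, st0$b)$d_amide == 0))

  # pure 0.3 ppm 1H offset inside the cluster, nothing outside
  st <- make_shift_tables(50, c(440, 445), cluster_amplitude = 0.3,
                          baseline_sd = 0, seed = 2)
  pr <- csp(st$a, st$b)
  inside <- pr$residue >= 440 & pr$residue <= 445
  expect_equal(pr$d_amide[inside], rep(0.3, sum(inside)), tolerance = 1e-12)
  expect_true(all(pr$d_amide[!inside] == 0))
  # Calpha untouched without baseline noise
  expect_equal(st$a$dCA_ppm, st$b$dCA_ppm)

  expect_error(make_shift_tables(20, c(1, 5)), "outside")
})

test_that("simulated thermograms peak near Tm and vanish without enthalpy", {
  m <- two_state_model(61.9, 110.1)
  tg <- make_thermogram(m, step = 0.5)
  expect_lte(abs(tg$temperature_c[which.max(tg$cp)] - 61.9), 0.5)

  flatm <- two_state_model(61.9, dh_cal = 0, dh_vh = 110,
                           baseline = c(0.4, 0))
  flat <- make_thermogram(flatm, step = 1)
  expect_equal(flat$cp, rep(0.4, nrow(flat)), tolerance = 1e-12)

  expect_error(make_thermogram(m, step = 0))
  expect_warning(make_thermogram(two_state_model(90, 100), 16, 80),
                 "window")
})

test_that("ensemble generator obeys its mode-variance construction", {
  ref <- rand_points(40, 5)
  # zero variance, zero jitter: every frame equals the reference
  still <- make_ensemble(ensemble_spec(ref, n_frames = 4, seed = 1))
  for (f in 1:4)
    expect_equal(matrix(still$coords[f, , ], ncol = 3), ref,
                 ignore_attr = TRUE)

  # two modes 3:1, no jitter: PC1 fraction 0.75 by construction
  modes <- collective_modes(ref, 2, seed = 6)
  ens <- make_ensemble(ensemble_spec(ref, modes, variances = c(3e-2, 1e-2),
                                     n_frames = 10000, seed = 8))
  pc <- pca_ensemble(ens, selection = "all")
  expect_equal(pc$fractions[1], 0.75, tolerance = 0.03)

  # non-orthonormal modes rejected
  badmode <- list(matrix(0.5, 40, 3))
  expect_error(ensemble_spec(ref, badmode, variances = 1), "orthonormal")
})

test_that("collective modes are orthonormal and free of rigid-body content", {
  ref <- rand_points(25, 9)
  modes <- collective_modes(ref, 3, seed = 2)
  v <- vapply(modes, function(m) as.numeric(t(m)), numeric(75))
  expect_equal(crossprod(v), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  # no net translation component
  for (m in modes) expect_lt(max(abs(colSums(m))), 1e-10)
})
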