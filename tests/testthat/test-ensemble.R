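test_that("Kabsch superposition removes exactly rigid motions", {
  p <- rand_points(10, 1)
  same <- kabsch_superpose(p, p)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  rot <- rot_from_axis_angle(c(0.4, -1.1, 2.0))
  moved <- p %*% rot + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  expect_lt(kabsch_superpose(p, moved)$rmsd, 1e-12)
  expect_true(abs(det(kabsch_superpose(p, moved)$rotation) - 1) < 1e-9)

  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("Kabsch rmsd equals a brute-force rotational search", {
  for (seed in c(3, 17, 101)) {
    p <- rand_points(10, seed)
    q <- rand_points(10, seed + 1000)
    expect_equal(kabsch_superpose(p, q)$rmsd, brute_force_rmsd(p, q),
                 tolerance = 1e-9)
  }
})

test_that("per-frame RMSD series behaves on degenerate and jittered ensembles", {
  ref <- rand_points(60, 4)
  rigid <- make_ensemble(ensemble_spec(ref, n_frames = 5, seed = 1))
  expect_true(all(rmsd_series(rigid) < 1e-12))

  shifted <- transform_ensemble(rigid, diag(3), c(5, 5, 5))
  expect_true(all(rmsd_series(shifted, reference = ref) < 1e-12))

  # iid jitter sigma: mean rmsd -> sigma sqrt(3 (1 - 1/n_atoms))
  sig <- 0.02
  jit <- make_ensemble(ensemble_spec(ref, jitter_sd = sig, n_frames = 800,
                                     seed = 2))
  r <- rmsd_series(jit, reference = ref)
  expect_equal(attr(r, "mean"), sig * sqrt(3 * (1 - 1 / 60)),
               tolerance = 0.02)
})

test_that("RMSF matches the analytic iid-jitter expectation", {
  ref <- rand_points(80, 6)
  rigid <- make_ensemble(ensemble_spec(ref, n_frames = 3, seed = 1))
  expect_true(all(rmsf(rigid) < 1e-12))

  sig <- 0.015
  jit <- make_ensemble(ensemble_spec(ref, jitter_sd = sig, n_frames = 3000,
                                     seed = 3))
  f <- rmsf(jit)
  expect_equal(mean(f), sig * sqrt(3), tolerance = 0.03)

  expect_error(rmsf(coord_ensemble(ref)), "2 frames")
})

test_that("one mobile atom among many fixed ones dominates the RMSF", {
  # superposition lets a lone mobile atom leak O(1/n_atoms) motion into the
  # rest, so with enough anchoring atoms its RMSF dwarfs all others
  ref <- rand_points(100, 7) * 2
  co <- array(0, dim = c(50, 100, 3))
  set.seed(8)
  for (f in 1:50) {
    x <- ref
    x[5, ] <- x[5, ] + rnorm(3, 0, 0.05)
    co[f, , ] <- x
  }
  f <- rmsf(coord_ensemble(co))
  expect_gt(f[5], 10 * max(f[-5]))
})

test_that("radius of gyration matches closed forms", {
  two <- matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(as.numeric(radius_of_gyration(two, masses = c(1, 1))), 1)
  expect_equal(as.numeric(radius_of_gyration(matrix(2, 5, 3),
                                             masses = rep(1, 5))), 0)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  ring <- cbind(1.7 * cos(th), 1.7 * sin(th), 0)
  expect_equal(as.numeric(radius_of_gyration(ring, masses = rep(1, 200))),
               1.7, tolerance = 1e-9)
  expect_error(radius_of_gyration(two, masses = c(0, 0)))
})

test_that("PCA recovers a planted collective mode", {
  ref <- rand_points(60, 10)
  modes <- collective_modes(ref, 1, seed = 11)
  jitter <- 0.01
  resid_var <- 3 * 60 * jitter^2
  spec <- ensemble_spec(ref, modes, variances = 3 * resid_var,
                        jitter_sd = jitter, n_frames = 1000, seed = 12)
  pc <- pca_ensemble(make_ensemble(spec))
  expect_equal(pc$fractions[1], 0.75, tolerance = 0.03 / 0.75)
  cosang <- abs(sum(pc$vectors[, 1] * as.numeric(t(modes[[1]]))))
  expect_gt(cosang, 0.99)
  # eigenvalue sum equals the covariance trace
  expect_equal(sum(pc$values), pc$trace, tolerance = 1e-9)
  # orthonormal eigenvectors
  g <- crossprod(pc$vectors[, 1:10])
  expect_equal(g, diag(10), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("isotropic jitter spreads variance over the non-rigid modes", {
  ref <- rand_points(20, 13)
  iso <- make_ensemble(ensemble_spec(ref, jitter_sd = 0.02, n_frames = 2000,
                                     seed = 14))
  pc <- pca_ensemble(iso, selection = "all")
  # 3N - 6 internal modes share the variance roughly evenly
  expect_lt(pc$fractions[1], 2.5 / (3 * 20 - 6))
})

test_that("ensemble statistics are invariant under a global rigid motion", {
  ref <- rand_points(40, 15)
  modes <- collective_modes(ref, 1, seed = 16)
  ens <- make_ensemble(ensemble_spec(ref, modes, variances = 0.05,
                                     jitter_sd = 0.01, n_frames = 200,
                                     seed = 17))
  rot <- rot_from_axis_angle(c(1.2, 0.3, -0.7))
  ens2 <- transform_ensemble(ens, rot, c(4, -1, 9))
  expect_equal(rmsd_series(ens2, reference = ref %*% rot +
                             matrix(c(4, -1, 9), 40, 3, byrow = TRUE)),
               rmsd_series(ens, reference = ref), tolerance = 1e-9)
  expect_equal(rmsf(ens2), rmsf(ens), tolerance = 1e-9)
  expect_equal(as.numeric(radius_of_gyration(ens2)),
               as.numeric(radius_of_gyration(ens)), tolerance = 1e-9)
  expect_equal(pca_ensemble(ens2)$values, pca_ensemble(ens)$values,
               tolerance = 1e-7)
})

test_that("Kabsch rmsd agrees with an established independent implementation", {
  p <- rand_points(25, 18); q <- rand_points(25, 19)
  ours <- kabsch_superpose(p, q)$rmsd
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(q)),
                           mobile = as.numeric(t(p)),
                           fixed.inds = 1:75, mobile.inds = 1:75)
  theirs <- bio3d::rmsd(as.numeric(t(q)), fitted)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("porcupine export encodes the mode as a paired-model displacement", {
  ref <- rand_points(30, 20) + 5
  modes <- collective_modes(ref, 1, seed = 21)
  ens <- make_ensemble(ensemble_spec(ref, modes, variances = 0.04,
                                     jitter_sd = 0.005, n_frames = 500,
                                     seed = 22))
  pc <- pca_ensemble(ens)
  f <- tempfile(fileext = ".pdb")
  out <- porcupine_export(pc, component = 1, scale = 2, file = f)
  disp <- out$displaced - out$mean
  expect_equal(sqrt(sum(disp^2)), 2 * sqrt(pc$values[1]), tolerance = 1e-9)
  # displacement direction matches the planted mode
  cosang <- abs(sum(disp * modes[[1]]) /
                  sqrt(sum(disp^2) * sum(modes[[1]]^2)))
  expect_gt(cosang, 0.99)
  # scale 0: identical models
  out0 <- porcupine_export(pc, component = 1, scale = 0,
                           file = tempfile(fileext = ".pdb"))
  expect_equal(out0$displaced, out0$mean)
  # the written file is a 2-model ensemble consistent at PDB precision
  back <- read_structure(f)
  expect_equal(n_frames(back), 2)
  expect_equal(matrix(back$coords[1, , ], ncol = 3), out$mean,
               tolerance = 1e-3, ignore_attr = TRUE)
})
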