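# Shared fixtures and independent oracles, built in code at test time.

# noiseless single-exponential series
exact_decay <- function(rate, delays = default_r1_delays(), i0 = 100,
                        residue = 430, experiment = "R1") {
  decay_series(residue, experiment, delays, i0 * exp(-rate * delays))
}

# random non-degenerate point cloud
rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3)
}

# rotation matrix from an axis-angle 3-vector (angle = |v|, axis = v/|v|)
rot_from_axis_angle <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-300) return(diag(3))
  k <- v / th
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

# Brute-force oracle for the optimal-superposition RMSD: minimize the
# weighted RMSD over rotations parameterized by axis-angle, from many
# random starts, entirely independent of the SVD path.
brute_force_rmsd <- function(mobile, target, n_starts = 24, seed = 99) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(target, 2, colMeans(target))
  obj <- function(v) {
    r <- rot_from_axis_angle(v)
    mean(rowSums((p %*% t(r) - q)^2))
  }
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- optim(runif(3, -pi, pi), obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 500))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 500))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# direct Pearson r^2, written out from the definition (oracle, independent
# of stats::cor)
pearson_r2 <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  (num * num) / (sum((x - mx)^2) * sum((y - my)^2))
}

# apply one global rigid motion to every frame of an ensemble
transform_ensemble <- function(ens, rot, shift) {
  co <- ens$coords
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- matrix(co[f, , ], ncol = 3) %*% rot +
      matrix(shift, dim(co)[2], 3, byrow = TRUE)
  coord_ensemble(co, atoms = ens$atoms)
}
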