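# Generators for every input kind the pipeline consumes, with known ground
# truth. Noise is Gaussian and independent per data point, matching the
# RMS-spectral-noise error model of the analysis stages; one seed per
# generator call drives all sub-streams.

#' Ground-truth relaxation profile for a small beta-sandwich domain
#'
#' Per-residue true R1, R2 and NOE emulating a ~125-residue Ig-fold domain
#' (default span 428-552, the numbering of the lamin A Ig domain): a rigid
#' core tumbling as one unit plus flexible stretches with depressed R2/R1
#' and NOE. Core defaults are the wild-type domain means (R1 1.682 s^-1,
#' R2 20.09 s^-1, NOE 0.793); flexible stretches default to residues
#' 444-448 and 471-479. True per-residue values are plausible smooth
#' shapes, not reconstructions of any measured profile.
#'
#' @param residues Integer residue numbers, strictly increasing.
#' @param core_r1,core_r2,core_noe Rigid-core rates (s^-1) and NOE.
#' @param flexible List of length-2 integer ranges with enhanced mobility.
#' @param flex_scale Fractional R2 reduction / R1 elevation in flexible
#'   stretches (0-1); NOE drops toward `flex_noe`.
#' @param flex_noe NOE floor inside flexible stretches.
#' @param missing Integer residue numbers with no observable peaks
#'   (omitted from all generated series); default none.
#' @return Object of class `ground_truth_profile` with vectors `residues`,
#'   `true_R1`, `true_R2`, `true_NOE` and the `missing` set.
#' @export
ground_truth_profile <- function(residues = 428:552,
                                 core_r1 = 1.682, core_r2 = 20.09,
                                 core_noe = 0.793,
                                 flexible = list(c(444, 448), c(471, 479)),
                                 flex_scale = 0.45, flex_noe = 0.35,
                                 missing = integer(0)) {
  stopifnot(all(diff(residues) > 0), core_r1 > 0, core_r2 > 0,
            flex_scale >= 0, flex_scale < 1)
  r1 <- rep(core_r1, length(residues))
  r2 <- rep(core_r2, length(residues))
  noe <- rep(core_noe, length(residues))
  for (rg in flexible) {
    idx <- which(residues >= rg[1] & residues <= rg[2])
    if (length(idx) == 0) next
    # smooth bump: full effect mid-stretch, tapering to the edges
    w <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
    r2[idx] <- r2[idx] * (1 - flex_scale * w)
    r1[idx] <- r1[idx] * (1 + 0.15 * w)
    noe[idx] <- noe[idx] - (core_noe - flex_noe) * w
  }
  stopifnot(all(r1 > 0), all(r2 > 0))
  structure(list(residues = as.integer(residues), true_R1 = r1, true_R2 = r2,
                 true_NOE = noe, missing = as.integer(missing)),
            class = "ground_truth_profile")
}

#' Default relaxation delay schedules
#'
#' The wild-type measurement schedules: eight R1 delays from 5 to 1200 ms
#' and eight R2 delays from 8.5 to 101.8 ms, in seconds.
#' @name delay_schedules
#' @export
default_r1_delays <- function() c(5, 65, 145, 245, 365, 525, 750, 1200) / 1000

#' @rdname delay_schedules
#' @export
default_r2_delays <- function() c(8.5, 17.0, 25.4, 34.0, 50.9, 68.0, 84.8,
                                  101.8) / 1000

#' Generate decay series and NOE pairs from a ground-truth profile
#'
#' Intensities are I0 exp(-rate * delay) plus Gaussian noise of SD
#' `noise_rms * I0`; NOE pairs satisfy I_sat = NOE * I_ref before noise.
#' Residues in the profile's `missing` set are omitted entirely.
#'
#' @param profile A [ground_truth_profile()].
#' @param delays_r1,delays_r2 Delay schedules in seconds, strictly
#'   increasing.
#' @param noise_rms Noise SD as a fraction of `i0` (>= 0).
#' @param i0 Reference intensity (> 0).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List with `decays` (list of [decay_series()], R1 then R2 per
#'   residue) and `noe` (list of [noe_pair()]).
#' @export
make_decay_series <- function(profile, delays_r1 = default_r1_delays(),
                              delays_r2 = default_r2_delays(),
                              noise_rms = 0.02, i0 = 100, seed = 1) {
  stopifnot(inherits(profile, "ground_truth_profile"),
            length(delays_r1) > 0, length(delays_r2) > 0,
            all(diff(delays_r1) > 0), all(diff(delays_r2) > 0),
            noise_rms >= 0, i0 > 0)
  set.seed(seed)
  keep <- !(profile$residues %in% profile$missing)
  decays <- list(); noes <- list()
  sd_abs <- noise_rms * i0
  for (i in which(keep)) {
    res <- profile$residues[i]
    y1 <- i0 * exp(-profile$true_R1[i] * delays_r1) +
      stats::rnorm(length(delays_r1), 0, sd_abs)
    y2 <- i0 * exp(-profile$true_R2[i] * delays_r2) +
      stats::rnorm(length(delays_r2), 0, sd_abs)
    decays[[length(decays) + 1]] <-
      decay_series(res, "R1", delays_r1, y1, noise_rms = sd_abs)
    decays[[length(decays) + 1]] <-
      decay_series(res, "R2", delays_r2, y2, noise_rms = sd_abs)
    i_ref <- i0 + stats::rnorm(1, 0, sd_abs)
    i_sat <- profile$true_NOE[i] * i0 + stats::rnorm(1, 0, sd_abs)
    noes[[length(noes) + 1]] <- noe_pair(res, i_sat, i_ref,
                                         noise_rms = sd_abs)
  }
  list(decays = decays, noe = noes)
}

#' Generate paired chemical-shift tables for two variants
#'
#' Variant A gets plausible backbone shifts (amide 1H ~ N(8.3, 0.45) ppm,
#' 15N ~ N(118.5, 3.5) ppm, Calpha ~ N(56, 7) ppm). Variant B equals A plus
#' independent Gaussian noise of SD `baseline_sd` in every column and an
#' additional amide 1H offset of `cluster_amplitude` inside the perturbed
#' cluster; Calpha columns carry baseline noise only.
#'
#' @param n_residues Number of residues (numbered from `start_residue`).
#' @param perturbed_cluster Length-2 residue-number range receiving the
#'   amide offset; must lie inside the residue span.
#' @param cluster_amplitude Amide 1H offset in ppm.
#' @param baseline_sd Baseline noise SD in ppm (all columns).
#' @param seed Integer seed.
#' @param start_residue First residue number (default 428).
#' @return List with elements `a` and `b`, each a shift table data frame
#'   (`residue_number`, `residue_name`, `dHN_ppm`, `dN_ppm`, `dCA_ppm`).
#' @export
make_shift_tables <- function(n_residues = 100,
                              perturbed_cluster = c(470, 480),
                              cluster_amplitude = 0.3, baseline_sd = 0.02,
                              seed = 1, start_residue = 428) {
  stopifnot(n_residues >= 1, baseline_sd >= 0)
  residues <- start_residue + seq_len(n_residues) - 1
  if (perturbed_cluster[1] < min(residues) ||
      perturbed_cluster[2] > max(residues))
    stop("perturbed_cluster lies outside the residue span")
  set.seed(seed)
  a <- data.frame(residue_number = residues,
                  residue_name = rep("X", n_residues),
                  dHN_ppm = stats::rnorm(n_residues, 8.3, 0.45),
                  dN_ppm = stats::rnorm(n_residues, 118.5, 3.5),
                  dCA_ppm = stats::rnorm(n_residues, 56, 7))
  b <- a
  b$dHN_ppm <- b$dHN_ppm + stats::rnorm(n_residues, 0, baseline_sd)
  b$dN_ppm <- b$dN_ppm + stats::rnorm(n_residues, 0, baseline_sd)
  b$dCA_ppm <- b$dCA_ppm + stats::rnorm(n_residues, 0, baseline_sd)
  in_cluster <- residues >= perturbed_cluster[1] &
    residues <= perturbed_cluster[2]
  b$dHN_ppm[in_cluster] <- b$dHN_ppm[in_cluster] + cluster_amplitude
  list(a = a, b = b)
}

#' Simulate a two-state DSC thermogram
#'
#' Cp(T) = baseline(T) + excess two-state heat capacity ([excess_cp()]) +
#' Gaussian noise.
#'
#' @param model A [two_state_model()].
#' @param t_min,t_max Scan window in Celsius (warns unless
#'   t_min < Tm < t_max).
#' @param step Temperature step in Celsius (> 0).
#' @param noise_sd Noise SD in kcal mol^-1 K^-1.
#' @param seed Integer seed.
#' @return A [thermogram()].
#' @export
make_thermogram <- function(model, t_min = 16, t_max = 80, step = 0.1,
                            noise_sd = 0, seed = 1) {
  stopifnot(inherits(model, "two_state_model"), step > 0, t_min < t_max)
  tm_c <- model$tm_k - 273.15
  if (tm_c <= t_min || tm_c >= t_max)
    warning("Tm lies outside the scan window; transition will be truncated")
  t_c <- seq(t_min, t_max, by = step)
  t_k <- t_c + 273.15
  cp <- model$baseline[1] + model$baseline[2] * (t_k - model$tm_k) +
    excess_cp(model, t_k)
  if (noise_sd > 0) {
    set.seed(seed)
    cp <- cp + stats::rnorm(length(cp), 0, noise_sd)
  }
  thermogram(t_c, cp)
}

#' Specification of a synthetic coordinate ensemble
#'
#' @param reference n_atoms x 3 reference coordinates in nm.
#' @param modes List of n_atoms x 3 mode matrices; mutually orthonormal as
#'   3N-vectors (checked to 1e-8).
#' @param variances Per-mode variances in nm^2 (>= 0).
#' @param jitter_sd Isotropic per-coordinate Gaussian jitter SD in nm.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param atoms Optional atom annotation data frame (`resno`, `elety`,
#'   `resid`); defaults to one CA per residue numbered from 1.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(reference, modes = list(), variances = numeric(0),
                          jitter_sd = 0, n_frames = 100, seed = 1,
                          atoms = NULL) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3, n_frames >= 2, jitter_sd >= 0,
            length(modes) == length(variances), all(variances >= 0))
  if (length(modes) > 0) {
    v <- vapply(modes, function(m) as.numeric(t(m)), numeric(3 * nrow(reference)))
    g <- crossprod(v)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      stop("mode vectors are not mutually orthonormal (tolerance 1e-8)")
  }
  if (is.null(atoms))
    atoms <- data.frame(resno = seq_len(nrow(reference)), elety = "CA",
                        resid = "ALA")
  structure(list(reference = reference, modes = modes, variances = variances,
                 jitter_sd = jitter_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), atoms = atoms),
            class = "ensemble_spec")
}

#' Random collective modes orthogonal to rigid-body motions
#'
#' Draws random 3N-direction(s), removes their projection onto the six
#' rigid-body motions of the reference (three translations, three
#' infinitesimal rotations), and orthonormalizes. Superposition removes
#' rigid-body displacement, so only modes orthogonal to that subspace carry
#' their nominal variance into aligned-ensemble statistics; planting such
#' modes makes variance fractions exact by construction.
#'
#' @param reference n_atoms x 3 coordinates (nm).
#' @param n_modes Number of modes to generate.
#' @param seed Integer seed.
#' @return List of n_atoms x 3 orthonormal mode matrices.
#' @export
collective_modes <- function(reference, n_modes = 1, seed = 1) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  stopifnot(n >= 3, n_modes >= 1)
  ctr <- sweep(reference, 2, colMeans(reference))
  # rigid-body basis: translations and infinitesimal rotations, as rows of
  # per-atom xyz stacked into 3N-vectors (atom-major, xyz within atom)
  flat <- function(m) as.numeric(t(m))
  basis <- cbind(
    flat(cbind(rep(1, n), 0, 0)), flat(cbind(0, rep(1, n), 0)),
    flat(cbind(0, 0, rep(1, n))),
    flat(cbind(0, -ctr[, 3], ctr[, 2])),
    flat(cbind(ctr[, 3], 0, -ctr[, 1])),
    flat(cbind(-ctr[, 2], ctr[, 1], 0)))
  basis <- qr.Q(qr(basis))
  set.seed(seed)
  out <- list()
  taken <- basis
  for (k in seq_len(n_modes)) {
    v <- stats::rnorm(3 * n)
    v <- v - taken %*% crossprod(taken, v)
    v <- v / sqrt(sum(v^2))
    taken <- cbind(taken, v)
    out[[k]] <- matrix(v, ncol = 3, byrow = TRUE)
  }
  out
}

#' Generate a coordinate ensemble from a mode specification
#'
#' Frame f = reference + sum_m a_fm mode_m + jitter, with mode amplitudes
#' a_fm ~ Normal(0, variance_m) and isotropic per-coordinate jitter.
#'
#' @param spec An [ensemble_spec()].
#' @return A [coord_ensemble()] carrying the spec's atom labels.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n_at <- nrow(spec$reference)
  coords <- array(0, dim = c(spec$n_frames, n_at, 3))
  amps <- matrix(0, spec$n_frames, length(spec$modes))
  for (m in seq_along(spec$modes))
    amps[, m] <- stats::rnorm(spec$n_frames, 0, sqrt(spec$variances[m]))
  for (f in seq_len(spec$n_frames)) {
    x <- spec$reference
    for (m in seq_along(spec$modes))
      x <- x + amps[f, m] * spec$modes[[m]]
    if (spec$jitter_sd > 0)
      x <- x + matrix(stats::rnorm(3 * n_at, 0, spec$jitter_sd), n_at, 3)
    coords[f, , ] <- x
  }
  coord_ensemble(coords, atoms = spec$atoms)
}
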