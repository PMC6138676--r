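# Rigid isotropic rotor model for backbone 15N relaxation:
# dipolar (N-H) + CSA mechanisms, no exchange term (Rex = 0 throughout).

#' Spin parameters for 15N relaxation calculations
#'
#' Bundles the spectrometer field and the physical constants that convert a
#' rotational correlation time into predicted 15N relaxation rates. Defaults
#' are the community values used by standard R2/R1 ratio-analysis tools:
#' N-H bond length 1.02 A and a 15N CSA of -160 ppm.
#'
#' @param field_mhz Proton Larmor frequency in MHz (> 0).
#' @param r_nh_angstrom N-H bond length in Angstrom (> 0).
#' @param csa_ppm 15N chemical shift anisotropy in ppm.
#' @param gamma_h Proton gyromagnetic ratio, rad s^-1 T^-1 (> 0).
#' @param gamma_n 15N gyromagnetic ratio, rad s^-1 T^-1 (< 0).
#' @return An object of class `spin_params`.
#' @examples
#' sp <- spin_params()
#' rates_from_tauc(10.7, sp)
#' @export
spin_params <- function(field_mhz = 600.13, r_nh_angstrom = 1.02,
                        csa_ppm = -160, gamma_h = 2.67522e8,
                        gamma_n = -2.7126e7) {
  stopifnot(field_mhz > 0, r_nh_angstrom > 0, gamma_h > 0, gamma_n < 0)
  structure(list(field_mhz = field_mhz, r_nh_angstrom = r_nh_angstrom,
                 csa_ppm = csa_ppm, gamma_h = gamma_h, gamma_n = gamma_n),
            class = "spin_params")
}

#' @export
print.spin_params <- function(x, ...) {
  cat(sprintf("15N spin parameters: %.2f MHz 1H, r_NH %.2f A, CSA %.0f ppm\n",
              x$field_mhz, x$r_nh_angstrom, x$csa_ppm))
  invisible(x)
}

# Angular frequencies and interaction constants. d is the dipolar coupling
# constant (rad/s); c the CSA constant. Returned in SI.
.spin_constants <- function(params) {
  mu0 <- 4 * pi * 1e-7
  h <- 6.62607015e-34
  r <- params$r_nh_angstrom * 1e-10
  w_h <- 2 * pi * params$field_mhz * 1e6
  w_n <- w_h * params$gamma_n / params$gamma_h
  d <- mu0 * h * params$gamma_h * params$gamma_n / (8 * pi^2 * r^3)
  cc <- w_n * params$csa_ppm * 1e-6 / sqrt(3)
  list(w_h = w_h, w_n = w_n, d2 = d^2, c2 = cc^2)
}

#' Lorentzian spectral density of an isotropic rigid rotor
#'
#' J(omega) = (2/5) tau_c / (1 + (omega tau_c)^2). Even in omega, so the sign
#' of the frequency is immaterial.
#'
#' @param omega Angular frequency, rad/s (vectorized).
#' @param tauc_s Rotational correlation time in seconds (> 0).
#' @return Spectral density in s/rad.
#' @export
spectral_density <- function(omega, tauc_s) {
  stopifnot(tauc_s > 0)
  0.4 * tauc_s / (1 + (omega * tauc_s)^2)
}

#' Predict R1, R2 and heteronuclear NOE from a correlation time
#'
#' Standard dipolar + CSA expressions for an amide 15N spin on an
#' isotropically tumbling rigid molecule, with no conformational-exchange
#' contribution to R2.
#'
#' @param tauc_ns Rotational correlation time in nanoseconds (> 0).
#' @param params A [spin_params()] object.
#' @return Named numeric vector with elements `R1`, `R2` (s^-1), `NOE`.
#' @export
rates_from_tauc <- function(tauc_ns, params = spin_params()) {
  stopifnot(tauc_ns > 0)
  k <- .spin_constants(params)
  tc <- tauc_ns * 1e-9
  J <- function(w) spectral_density(w, tc)
  r1 <- (k$d2 / 4) * (J(k$w_h - k$w_n) + 3 * J(k$w_n) + 6 * J(k$w_h + k$w_n)) +
    k$c2 * J(k$w_n)
  r2 <- (k$d2 / 8) * (4 * J(0) + J(k$w_h - k$w_n) + 3 * J(k$w_n) +
                        6 * J(k$w_h) + 6 * J(k$w_h + k$w_n)) +
    (k$c2 / 6) * (4 * J(0) + 3 * J(k$w_n))
  noe <- 1 + (k$d2 / (4 * r1)) * (params$gamma_h / params$gamma_n) *
    (6 * J(k$w_h + k$w_n) - J(k$w_h - k$w_n))
  c(R1 = r1, R2 = r2, NOE = noe)
}

#' Invert the R2/R1 ratio for the rotational correlation time
#'
#' Solves rates_from_tauc(tau)\["R2"\] / rates_from_tauc(tau)\["R1"\] = ratio by
#' bracketed root finding on the given tau_c interval. The ratio is verified
#' to be monotonically increasing on the bracket before solving, so the root
#' is unique.
#'
#' @param ratio Dimensionless R2/R1 ratio (>= 1).
#' @param params A [spin_params()] object.
#' @param bracket_ns Length-2 search interval for tau_c in ns.
#' @return Rotational correlation time in ns.
#' @examples
#' estimate_tauc(12.18)  # ~10.7 ns at 600.13 MHz
#' @export
estimate_tauc <- function(ratio, params = spin_params(),
                          bracket_ns = c(0.1, 100)) {
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio >= 1,
            length(bracket_ns) == 2, bracket_ns[1] > 0,
            bracket_ns[1] < bracket_ns[2])
  ratio_at <- function(tc) {
    r <- rates_from_tauc(tc, params)
    unname(r["R2"] / r["R1"])
  }
  grid <- exp(seq(log(bracket_ns[1]), log(bracket_ns[2]), length.out = 64))
  rg <- vapply(grid, ratio_at, numeric(1))
  if (any(diff(rg) <= 0))
    stop("R2/R1 is not monotonic on the bracket; cannot invert uniquely")
  lo <- ratio_at(bracket_ns[1]); hi <- ratio_at(bracket_ns[2])
  if (ratio < lo || ratio > hi)
    stop(sprintf("ratio %.3f outside model range [%.3f, %.3f] on bracket",
                 ratio, lo, hi))
  uniroot(function(tc) ratio_at(tc) - ratio, interval = bracket_ns,
          tol = 1e-9 * mean(bracket_ns))$root
}

#' Closed-form high-field approximation to the R2/R1 inversion
#'
#' tau_c ~ sqrt(6 ratio - 7) / (4 pi nu_N); used as an independent
#' cross-check of the full numerical inversion.
#'
#' @inheritParams estimate_tauc
#' @return Approximate tau_c in ns.
#' @export
tauc_quadratic_approx <- function(ratio, params = spin_params()) {
  stopifnot(ratio >= 7 / 6)
  nu_n <- params$field_mhz * 1e6 * abs(params$gamma_n) / params$gamma_h
  1e9 * sqrt(6 * ratio - 7) / (4 * pi * nu_n)
}

#' Select residues reporting on overall tumbling
#'
#' Applies the standard exclusion rules before estimating a global tumbling
#' time from R2/R1: residues whose ratio lies more than `sd_mult` sample
#' standard deviations above or below the mean ratio are excluded as carrying
#' local dynamics or exchange, and residues whose heteronuclear NOE lies more
#' than `sd_mult` SD below the mean NOE are excluded as flexible. Rules are
#' applied independently; strict inequalities, so boundary ties are kept.
#'
#' @param records Relaxation record data frame (see [fit_relaxation()]), with
#'   columns `residue`, `R1`, `R2` and optionally `NOE`.
#' @param sd_mult Exclusion multiplier (default 1 SD).
#' @return A list with `used` (data frame of surviving records, plus their
#'   `ratio`), `excluded` (data frame residue/reason, reasons in
#'   `ratio_high`, `ratio_low`, `low_noe`, `missing`), `mean_ratio` and
#'   `sd_ratio` over the residues entering the rule.
#' @export
filter_for_diffusion <- function(records, sd_mult = 1) {
  stopifnot(is.data.frame(records), all(c("residue", "R1", "R2") %in%
                                          names(records)))
  has_both <- !is.na(records$R1) & !is.na(records$R2)
  if (sum(has_both) < 3)
    stop("need at least 3 records with both R1 and R2")
  excl <- data.frame(residue = integer(0), reason = character(0))
  if (any(!has_both))
    excl <- rbind(excl, data.frame(residue = records$residue[!has_both],
                                   reason = "missing"))
  rec <- records[has_both, , drop = FALSE]
  rec$ratio <- rec$R2 / rec$R1
  m <- mean(rec$ratio); s <- stats::sd(rec$ratio)
  bad_hi <- rec$ratio > m + sd_mult * s
  bad_lo <- rec$ratio < m - sd_mult * s
  bad_noe <- rep(FALSE, nrow(rec))
  if ("NOE" %in% names(rec) && sum(!is.na(rec$NOE)) >= 2) {
    noe_ok <- !is.na(rec$NOE)
    m_noe <- mean(rec$NOE[noe_ok]); s_noe <- stats::sd(rec$NOE[noe_ok])
    bad_noe <- noe_ok & rec$NOE < m_noe - sd_mult * s_noe
  }
  if (any(bad_hi))
    excl <- rbind(excl, data.frame(residue = rec$residue[bad_hi],
                                   reason = "ratio_high"))
  if (any(bad_lo))
    excl <- rbind(excl, data.frame(residue = rec$residue[bad_lo],
                                   reason = "ratio_low"))
  if (any(bad_noe & !bad_hi & !bad_lo))
    excl <- rbind(excl,
                  data.frame(residue = rec$residue[bad_noe & !bad_hi & !bad_lo],
                             reason = "low_noe"))
  keep <- !(bad_hi | bad_lo | bad_noe)
  list(used = rec[keep, , drop = FALSE], excluded = excl,
       mean_ratio = m, sd_ratio = s)
}

#' Estimate the global rotational correlation time from relaxation records
#'
#' Convenience wrapper: applies [filter_for_diffusion()], averages the R2/R1
#' ratio over the surviving residues, and inverts it with [estimate_tauc()].
#'
#' @inheritParams filter_for_diffusion
#' @inheritParams estimate_tauc
#' @return A list of class `diffusion_result`: `tauc_ns`, `mean_ratio` and
#'   `sd_ratio` of the ratios actually used, `used`, `excluded`.
#' @export
tauc_from_records <- function(records, params = spin_params(), sd_mult = 1,
                              bracket_ns = c(0.1, 100)) {
  f <- filter_for_diffusion(records, sd_mult = sd_mult)
  if (nrow(f$used) < 1) stop("no residues survive the exclusion rules")
  mean_used <- mean(f$used$ratio)
  res <- list(tauc_ns = estimate_tauc(mean_used, params, bracket_ns),
              mean_ratio = mean_used,
              sd_ratio = if (nrow(f$used) > 1) stats::sd(f$used$ratio) else 0,
              used = f$used, excluded = f$excluded)
  class(res) <- "diffusion_result"
  res
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("tau_c = %.2f ns from mean R2/R1 = %.2f +/- %.2f (%d used, %d excluded)\n",
              x$tauc_ns, x$mean_ratio, x$sd_ratio, nrow(x$used),
              nrow(x$excluded)))
  invisible(x)
}
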