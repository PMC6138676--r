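# Extraction of per-residue R1/R2/NOE from peak-intensity data.
# Model: I(t) = I0 * exp(-R t), two parameters, no offset (offset optional).

#' Construct an intensity decay series for one residue
#'
#' @param residue Integer residue number.
#' @param experiment `"R1"` or `"R2"`.
#' @param delays Relaxation delays in seconds; strictly increasing, >= 0,
#'   at least 4 points.
#' @param intensities Peak intensities (arbitrary units), same length.
#' @param noise_rms RMS spectral noise in intensity units (>= 0).
#' @return Object of class `decay_series`.
#' @export
decay_series <- function(residue, experiment, delays, intensities,
                         noise_rms = 0) {
  experiment <- match.arg(experiment, c("R1", "R2"))
  stopifnot(length(delays) == length(intensities), length(delays) >= 4,
            all(delays >= 0), all(diff(delays) > 0), noise_rms >= 0,
            all(is.finite(intensities)))
  structure(list(residue = as.integer(residue), experiment = experiment,
                 delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 noise_rms = noise_rms),
            class = "decay_series")
}

#' Construct a saturated/reference intensity pair for the heteronuclear NOE
#'
#' @param residue Integer residue number.
#' @param intensity_sat Intensity with proton presaturation.
#' @param intensity_ref Intensity without presaturation (non-zero).
#' @param noise_rms RMS spectral noise shared by the two spectra.
#' @return Object of class `noe_pair`.
#' @export
noe_pair <- function(residue, intensity_sat, intensity_ref, noise_rms = 0) {
  stopifnot(intensity_ref != 0, noise_rms >= 0)
  structure(list(residue = as.integer(residue),
                 intensity_sat = intensity_sat,
                 intensity_ref = intensity_ref, noise_rms = noise_rms),
            class = "noe_pair")
}

# Core exponential fit. Log-linear regression on positive intensities seeds
# a Levenberg-Marquardt refinement; if no intensities are positive the seed
# comes from a coarse rate grid instead.
.fit_exp <- function(delays, intensities, offset = FALSE) {
  pos <- intensities > 0
  if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(intensities[pos]) ~ delays[pos]))
    start <- list(i0 = exp(co[[1]]), r = max(-co[[2]], 1e-6))
  } else {
    rates <- 10^seq(-2, 3, length.out = 40)
    sse <- vapply(rates, function(r) {
      b <- exp(-r * delays)
      i0 <- sum(b * intensities) / sum(b * b)
      sum((intensities - i0 * b)^2)
    }, numeric(1))
    r0 <- rates[which.min(sse)]
    b <- exp(-r0 * delays)
    start <- list(i0 = sum(b * intensities) / sum(b * b), r = r0)
  }
  df <- data.frame(t = delays, y = intensities)
  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(y ~ i0 * exp(-r * t) + c0, data = df,
                        start = c(start, list(c0 = 0)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ i0 * exp(-r * t), data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(list(converged = FALSE))
  cf <- stats::coef(fit)
  list(converged = TRUE, rate = unname(cf["r"]), amplitude = unname(cf["i0"]),
       offset = if (offset) unname(cf["c0"]) else 0)
}

#' Fit a single-exponential decay to one residue's intensity series
#'
#' Least-squares fit of I(t) = I0 exp(-R t). The rate uncertainty, when
#' requested, comes from Monte-Carlo resampling of the best-fit curve with
#' the series' spectral noise ([mc_errors()]).
#'
#' @param series A [decay_series()].
#' @param mc_draws Monte-Carlo draws for the rate uncertainty; 0 skips the
#'   error estimate (returns `NA`).
#' @param seed Seed for the Monte-Carlo noise stream.
#' @param offset If `TRUE`, fit an additive baseline offset as a third
#'   parameter (off by default: the decays are modelled as pure single
#'   exponentials).
#' @return List with `rate` (s^-1), `amplitude`, `sigma_rate`, `converged`.
#' @examples
#' s <- decay_series(428, "R1", c(0, .25, .5, 1), 100 * exp(-1.3863 * c(0, .25, .5, 1)))
#' fit_decay(s, mc_draws = 0)$rate  # ln 2 / 0.5
#' @export
fit_decay <- function(series, mc_draws = 500, seed = 1, offset = FALSE) {
  stopifnot(inherits(series, "decay_series"))
  f <- .fit_exp(series$delays, series$intensities, offset = offset)
  if (!f$converged || !is.finite(f$rate) || f$rate <= 0)
    return(list(rate = NA_real_, amplitude = NA_real_, sigma_rate = NA_real_,
                converged = FALSE))
  sig <- if (mc_draws > 0)
    mc_errors(series, n_draws = mc_draws, seed = seed, offset = offset)
  else NA_real_
  list(rate = f$rate, amplitude = f$amplitude, sigma_rate = sig,
       converged = TRUE)
}

#' Monte-Carlo uncertainty of a fitted decay rate
#'
#' Adds Gaussian noise of SD `noise_rms` to the best-fit curve, refits, and
#' reports the standard deviation of the refit rates. This is the
#' spectral-noise-driven error model: the only stochastic input is the RMS
#' noise of the spectra.
#'
#' @inheritParams fit_decay
#' @param n_draws Number of synthetic datasets (>= 100; fewer gives an
#'   unstable SD and is rejected).
#' @return `sigma_rate` in s^-1 (0 when `noise_rms` is 0).
#' @export
mc_errors <- function(series, n_draws = 500, seed = 1, offset = FALSE) {
  stopifnot(inherits(series, "decay_series"))
  if (n_draws < 100) stop("n_draws must be >= 100 for a stable SD")
  if (series$noise_rms == 0) return(0)
  f <- .fit_exp(series$delays, series$intensities, offset = offset)
  if (!f$converged) return(NA_real_)
  ideal <- f$amplitude * exp(-f$rate * series$delays) + f$offset
  set.seed(seed)
  rates <- vapply(seq_len(n_draws), function(i) {
    y <- ideal + stats::rnorm(length(ideal), 0, series$noise_rms)
    g <- .fit_exp(series$delays, y, offset = offset)
    if (g$converged) g$rate else NA_real_
  }, numeric(1))
  stats::sd(rates, na.rm = TRUE)
}

#' Heteronuclear NOE from a saturated/reference intensity pair
#'
#' NOE = I_sat / I_ref, with the uncertainty propagated from one shared RMS
#' spectral noise:
#' sigma = |NOE| sqrt((noise/I_sat)^2 + (noise/I_ref)^2).
#'
#' @param pair A [noe_pair()].
#' @return List with `noe` and `sigma_noe`.
#' @export
compute_noe <- function(pair) {
  stopifnot(inherits(pair, "noe_pair"))
  noe <- pair$intensity_sat / pair$intensity_ref
  sig <- abs(noe) * sqrt((pair$noise_rms / pair$intensity_sat)^2 +
                           (pair$noise_rms / pair$intensity_ref)^2)
  list(noe = noe, sigma_noe = sig)
}

#' Fit all decay series and NOE pairs into a relaxation record table
#'
#' Runs [fit_decay()] on every series and [compute_noe()] on every pair,
#' assembling the per-residue record table that all downstream dynamics
#' analysis consumes. Non-converged fits yield `NA` for that component (with
#' a message naming the residue), never an abort.
#'
#' @param decays List of [decay_series()] (R1 and R2 experiments mixed).
#' @param noe_pairs List of [noe_pair()] (may be empty).
#' @param mc_draws Monte-Carlo draws per rate error (default 500).
#' @param seed Base seed; each series gets a distinct derived seed.
#' @return Data frame with columns `residue`, `R1`, `R1_err`, `R2`,
#'   `R2_err`, `NOE`, `NOE_err`, one row per residue, sorted by residue.
#' @export
fit_relaxation <- function(decays, noe_pairs = list(), mc_draws = 500,
                           seed = 1) {
  stopifnot(is.list(decays))
  residues <- sort(unique(c(
    vapply(decays, function(d) d$residue, integer(1)),
    vapply(noe_pairs, function(p) p$residue, integer(1)))))
  out <- data.frame(residue = residues, R1 = NA_real_, R1_err = NA_real_,
                    R2 = NA_real_, R2_err = NA_real_, NOE = NA_real_,
                    NOE_err = NA_real_)
  for (i in seq_along(decays)) {
    d <- decays[[i]]
    f <- fit_decay(d, mc_draws = mc_draws, seed = seed + i)
    row <- match(d$residue, out$residue)
    if (!f$converged) {
      message(sprintf("decay fit did not converge: residue %d %s",
                      d$residue, d$experiment))
      next
    }
    out[[d$experiment]][row] <- f$rate
    out[[paste0(d$experiment, "_err")]][row] <- f$sigma_rate
  }
  for (p in noe_pairs) {
    n <- compute_noe(p)
    row <- match(p$residue, out$residue)
    out$NOE[row] <- n$noe
    out$NOE_err[row] <- n$sigma_noe
  }
  out
}

#' Summary statistics over a relaxation record table
#'
#' Mean and sample SD (n-1) of R1, R2, NOE and the R2/R1 ratio over residues
#' where each quantity is defined. The ratio is computed per residue where
#' both rates are present and then averaged (mean of ratios, not ratio of
#' means). A component with a single observation reports SD 0 with
#' `sd_defined = FALSE`.
#'
#' @param records Data frame as returned by [fit_relaxation()].
#' @return Data frame with rows R1, R2, NOE, R2_R1 and columns `mean`, `sd`,
#'   `n`, `sd_defined`.
#' @export
summarize_records <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(mean = NA_real_, sd = NA_real_, n = 0L,
                        sd_defined = FALSE))
    data.frame(mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               n = length(x), sd_defined = length(x) > 1)
  }
  ratio <- ifelse(!is.na(records$R1) & !is.na(records$R2),
                  records$R2 / records$R1, NA_real_)
  out <- rbind(one(records$R1), one(records$R2), one(records$NOE), one(ratio))
  rownames(out) <- c("R1", "R2", "NOE", "R2_R1")
  out
}
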