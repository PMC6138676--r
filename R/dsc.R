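# Two-state DSC unfolding: simulate, integrate and fit excess heat-capacity
# curves. Temperatures are kelvin internally, Celsius at every interface,
# matching calorimetry reporting conventions. Gas constant in kcal.

.R_GAS <- 1.9872e-3  # kcal mol^-1 K^-1

#' Two-state unfolding model
#'
#' Parameters of a folded-unfolded equilibrium observed by DSC: midpoint
#' temperature, van't Hoff enthalpy (sets the transition sharpness),
#' calorimetric enthalpy (sets the peak area), and a linear instrumental
#' baseline. The two enthalpies are independent parameters: their ratio is
#' a diagnostic of two-state behavior and of coupled oligomer dissociation.
#'
#' @param tm_c Midpoint temperature in Celsius.
#' @param dh_cal Calorimetric enthalpy, kcal/mol.
#' @param dh_vh van't Hoff enthalpy, kcal/mol (> 0); defaults to `dh_cal`.
#' @param baseline Length-2 `c(intercept, slope)` of the linear baseline in
#'   kcal mol^-1 K^-1 (slope per K, centered at Tm).
#' @return Object of class `two_state_model` (Tm stored in kelvin as
#'   `tm_k`).
#' @export
two_state_model <- function(tm_c, dh_cal, dh_vh = dh_cal,
                            baseline = c(0, 0)) {
  stopifnot(tm_c > -273.15, dh_vh > 0, length(baseline) == 2)
  structure(list(tm_k = tm_c + 273.15, dh_cal = dh_cal, dh_vh = dh_vh,
                 baseline = as.numeric(baseline)),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf("two-state model: Tm %.2f C, dH_cal %.1f, dH_vH %.1f kcal/mol\n",
              x$tm_k - 273.15, x$dh_cal, x$dh_vh))
  invisible(x)
}

#' DSC thermogram container
#'
#' @param temperature_c Temperatures in Celsius, strictly increasing.
#' @param cp Molar heat capacity, kcal mol^-1 K^-1.
#' @param scan_rate_c_per_h,concentration_um Metadata, carried but unused by
#'   the equilibrium analysis.
#' @return Data frame of class `thermogram` with columns `temperature_c`,
#'   `cp`; kelvin available via `thermogram_kelvin()`.
#' @export
thermogram <- function(temperature_c, cp, scan_rate_c_per_h = 30,
                       concentration_um = NA_real_) {
  stopifnot(length(temperature_c) == length(cp),
            all(diff(temperature_c) > 0))
  structure(data.frame(temperature_c = temperature_c, cp = cp),
            scan_rate_c_per_h = scan_rate_c_per_h,
            concentration_um = concentration_um,
            class = c("thermogram", "data.frame"))
}

#' @rdname thermogram
#' @param x A `thermogram`.
#' @export
thermogram_kelvin <- function(x) x$temperature_c + 273.15

#' Excess heat capacity of a two-state transition
#'
#' With K(T) = exp(-(dH_vH/R)(1/T - 1/Tm)),
#' Cp_exc(T) = dH_cal dH_vH K / (R T^2 (1+K)^2). The integral of this curve
#' over temperature is exactly dH_cal — the defining relation between peak
#' area and calorimetric enthalpy.
#'
#' @param model A [two_state_model()].
#' @param t_k Temperatures in kelvin (vectorized, > 0).
#' @return Excess Cp in kcal mol^-1 K^-1 (baseline not included).
#' @export
excess_cp <- function(model, t_k) {
  stopifnot(inherits(model, "two_state_model"), all(t_k > 0))
  lnK <- -(model$dh_vh / .R_GAS) * (1 / t_k - 1 / model$tm_k)
  # K/(1+K)^2 computed as f(1-f) with f = plogis(lnK) for overflow safety
  f <- stats::plogis(lnK)
  model$dh_cal * model$dh_vh * f * (1 - f) / (.R_GAS * t_k^2)
}

# Linear baseline from the non-transition part of the scan: an initial fit
# to the outer flanks (default outer 15% per side) is refined twice by
# excluding every point whose provisional excess exceeds 0.1% of the peak
# height, which keeps the slowly decaying transition tails from biasing the
# flank fit. At least 5 points must survive on each side of the peak.
# Returns c(intercept, slope) in Cp = a + b * T_K.
.auto_baseline <- function(tg, flank_fraction = 0.15) {
  n <- nrow(tg)
  k <- max(5, floor(flank_fraction * n))
  if (2 * k >= n) stop("too few points to determine flank baseline")
  t_k <- thermogram_kelvin(tg)
  use <- c(rep(TRUE, k), rep(FALSE, n - 2 * k), rep(TRUE, k))
  co <- stats::coef(stats::lm(tg$cp[use] ~ t_k[use]))
  for (i in 1:2) {
    exc <- tg$cp - (co[[1]] + co[[2]] * t_k)
    pk <- which.max(exc)
    keep <- exc < 1e-3 * max(exc)
    if (sum(keep[seq_len(pk)]) < 5 || sum(keep[pk:n]) < 5) break
    co <- stats::coef(stats::lm(tg$cp[keep] ~ t_k[keep]))
  }
  co
}

.baseline_values <- function(tg, baseline) {
  t_k <- thermogram_kelvin(tg)
  if (is.character(baseline) && baseline == "auto") {
    co <- .auto_baseline(tg)
    co[[1]] + co[[2]] * t_k
  } else if (is.character(baseline) && baseline == "zero") {
    rep(0, nrow(tg))
  } else {
    stopifnot(is.numeric(baseline), length(baseline) == 2)
    baseline[1] + baseline[2] * t_k
  }
}

#' Calorimetric enthalpy by integrating the thermogram
#'
#' Trapezoidal integral of (Cp - baseline) over the scan window:
#' dH_cal = integral of excess Cp dT.
#'
#' @param tg A [thermogram()].
#' @param baseline `"auto"` (linear fit to the outer 15% flanks), `"zero"`,
#'   or explicit `c(intercept, slope)` versus kelvin.
#' @return dH_cal in kcal/mol, with attribute `truncated = TRUE` (and a
#'   warning) when the peak sits within 3 points of a scan edge.
#' @export
integrate_enthalpy <- function(tg, baseline = "auto") {
  stopifnot(inherits(tg, "thermogram"), nrow(tg) >= 10)
  exc <- tg$cp - .baseline_values(tg, baseline)
  pk <- which.max(exc)
  trunc <- pk - 1 <= 3 || nrow(tg) - pk <= 3
  if (trunc)
    warning("transition peak lies at the edge of the scan window; enthalpy is truncated")
  structure(pracma::trapz(thermogram_kelvin(tg), exc), truncated = trunc)
}

#' Transition midpoint from the thermogram maximum
#'
#' Temperature of the maximum of baseline-subtracted Cp, refined by
#' parabolic interpolation through the three points around the grid
#' maximum.
#'
#' @inheritParams integrate_enthalpy
#' @return Tm in Celsius.
#' @export
find_tm <- function(tg, baseline = "auto") {
  stopifnot(inherits(tg, "thermogram"), nrow(tg) >= 10)
  exc <- tg$cp - .baseline_values(tg, baseline)
  i <- which.max(exc)
  if (i == 1 || i == nrow(tg))
    stop("no interior maximum: thermogram shows no transition in the window")
  t3 <- tg$temperature_c[(i - 1):(i + 1)]
  y3 <- exc[(i - 1):(i + 1)]
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (denom == 0) return(t3[2])
  # vertex of the parabola through the three bracketing points
  t3[2] + 0.5 * (t3[2] - t3[1]) * (y3[1] - y3[3]) / denom
}

#' Fit a two-state model to a thermogram
#'
#' Nonlinear least squares of baseline + [excess_cp()] with free Tm,
#' dH_vH, dH_cal and linear baseline, initialized from [find_tm()] and
#' [integrate_enthalpy()]. Non-convergence after bounded restarts returns
#' the initial estimates flagged as unconverged rather than aborting.
#'
#' @param tg A [thermogram()] (>= 10 points spanning the transition).
#' @return List of class `twostate_fit`: `model` ([two_state_model()]),
#'   `rms_residual`, `converged`.
#' @export
fit_twostate <- function(tg) {
  stopifnot(inherits(tg, "thermogram"), nrow(tg) >= 10)
  t_k <- thermogram_kelvin(tg)
  tm0 <- find_tm(tg, baseline = "auto") + 273.15
  dh0 <- as.numeric(integrate_enthalpy(tg, baseline = "auto"))
  if (!is.finite(dh0) || dh0 <= 0) dh0 <- 50
  bl0 <- .auto_baseline(tg)
  model_fun <- function(tm, dhvh, dhcal, b0, b1) {
    m <- two_state_model(tm - 273.15, dh_cal = dhcal, dh_vh = max(dhvh, 1))
    b0 + b1 * (t_k - tm) + excess_cp(m, t_k)
  }
  df <- data.frame(y = tg$cp)
  starts <- list(
    list(tm = tm0, dhvh = dh0, dhcal = dh0,
         b0 = bl0[[1]] + bl0[[2]] * tm0, b1 = bl0[[2]]),
    list(tm = tm0, dhvh = 0.5 * dh0, dhcal = dh0,
         b0 = bl0[[1]] + bl0[[2]] * tm0, b1 = bl0[[2]]),
    list(tm = tm0, dhvh = 2 * dh0, dhcal = dh0,
         b0 = bl0[[1]] + bl0[[2]] * tm0, b1 = bl0[[2]]))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ model_fun(tm, dhvh, dhcal, b0, b1), data = df,
                        start = st,
                        lower = c(min(t_k), 1, -Inf, -Inf, -Inf),
                        upper = c(max(t_k), 5000, Inf, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rms <- sqrt(mean(stats::resid(fit)^2))
      if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
    }
  }
  if (is.null(best)) {
    warning("two-state fit did not converge; returning initial estimates")
    return(structure(list(
      model = two_state_model(tm0 - 273.15, dh_cal = dh0, dh_vh = dh0,
                              baseline = c(bl0[[1]] + bl0[[2]] * tm0,
                                           bl0[[2]])),
      rms_residual = NA_real_, converged = FALSE), class = "twostate_fit"))
  }
  cf <- stats::coef(best$fit)
  model <- two_state_model(cf[["tm"]] - 273.15, dh_cal = cf[["dhcal"]],
                           dh_vh = cf[["dhvh"]],
                           baseline = c(cf[["b0"]], cf[["b1"]]))
  structure(list(model = model, rms_residual = best$rms, converged = TRUE),
            class = "twostate_fit")
}

#' @export
print.twostate_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  rms residual %.4g, converged: %s\n", x$rms_residual,
              x$converged))
  invisible(x)
}
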