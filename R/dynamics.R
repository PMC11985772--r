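#' System properties for the force model
#'
#' @param mt total mass of athlete plus wheelchair, kg.
#' @param mu_r rolling-resistance coefficient (unitless), typically from a
#'   coast-down test via [estimate_rolling_resistance()].
#' @param kf speed-on-friction coefficient, s^2/m^2 (default 0).
#' @param CdA drag coefficient times frontal area, m^2.
#' @param rho air density, kg/m^3 (default 1.22).
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `system_properties`.
#' @export
system_properties <- function(mt, mu_r = 0, kf = 0, CdA = 0,
                              rho = 1.22, g = 9.81) {
  check_positive(mt, "mt")
  check_nonneg(mu_r, "mu_r")
  check_nonneg(kf, "kf")
  check_nonneg(CdA, "CdA")
  check_positive(rho, "rho")
  structure(list(mt = mt, mu_r = mu_r, kf = kf, CdA = CdA, rho = rho, g = g),
            class = "system_properties")
}

#' Fit the 4th-degree velocity polynomial
#'
#' Least-squares fit of `pV(x) = p1 x^4 + p2 x^3 + p3 x^2 + p4 x + p5` to the
#' velocity trace, with time re-origined to the sprint start (`x = t - t[1]`).
#' The polynomial smooths intra-stroke velocity variation so that acceleration
#' can be taken as its analytic derivative.
#'
#' @param t time series, seconds (>= 5 samples, distinct).
#' @param v velocity series, m/s.
#' @return An object of class `velocity_polynomial`: `coeffs` (p1..p5,
#'   descending powers), `domain` in re-origined time, `t0`, the fitting grid
#'   `x`, and `fit_residual_rms` (m/s).
#' @export
fit_velocity_polynomial <- function(t, v) {
  if (length(t) != length(v)) {
    stop("fit_velocity_polynomial: t and v must share length", call. = FALSE)
  }
  if (length(t) < 5L) {
    stop("fit_velocity_polynomial: need at least 5 samples", call. = FALSE)
  }
  if (anyDuplicated(t)) {
    stop("fit_velocity_polynomial: duplicate times make the design rank-deficient",
         call. = FALSE)
  }
  x <- t - t[1]
  X <- cbind(x^4, x^3, x^2, x, 1)
  fit <- stats::lm.fit(X, v)
  if (fit$rank < 5L) {
    stop("fit_velocity_polynomial: rank-deficient design", call. = FALSE)
  }
  coeffs <- unname(fit$coefficients)
  structure(list(coeffs = coeffs, domain = c(0, x[length(x)]), t0 = t[1], x = x,
                 fit_residual_rms = sqrt(mean(fit$residuals^2))),
            class = "velocity_polynomial")
}

#' Evaluate a fitted velocity polynomial (or its derivative)
#'
#' @param poly a [fit_velocity_polynomial()] result.
#' @param x evaluation points in re-origined time (within `poly$domain`).
#' @param deriv 0 for velocity, 1 for acceleration.
#' @return Numeric series.
#' @export
eval_velocity_polynomial <- function(poly, x, deriv = 0L) {
  eps <- 1e-9
  if (any(x < poly$domain[1] - eps | x > poly$domain[2] + eps)) {
    stop("eval_velocity_polynomial: evaluation outside fitted domain", call. = FALSE)
  }
  p <- poly$coeffs
  if (deriv == 0L) {
    ((((p[1] * x + p[2]) * x + p[3]) * x + p[4]) * x) + p[5]
  } else if (deriv == 1L) {
    ((4 * p[1] * x + 3 * p[2]) * x + 2 * p[3]) * x + p[4]
  } else {
    stop("eval_velocity_polynomial: deriv must be 0 or 1", call. = FALSE)
  }
}

#' Estimate the rolling-resistance coefficient from coast-down trials
#'
#' Per trial, the coast deceleration is the (negated) ordinary-least-squares
#' slope of the wheel-derived speed over the interval from 0.5 s after the end
#' of the push to 0.5 s before the chair is stopped; the coefficient is the
#' two-direction average deceleration divided by g, which cancels any
#' direction-antisymmetric bias such as a track grade.
#'
#' @param trial_pair list of two coast-down [imu_stream()]s (opposite
#'   directions) carrying `push_end_t` and `stop_t` metadata.
#' @param geometry [wheel_geometry()] of the instrumented wheel.
#' @param system a [system_properties()] (for g).
#' @param trim_s interval trimmed off each end of the coast phase, seconds.
#' @return The estimated `mu_r`, with per-trial decelerations (m/s^2) in
#'   attribute `"decel"`.
#' @export
estimate_rolling_resistance <- function(trial_pair, geometry, system,
                                        trim_s = 0.5) {
  if (length(trial_pair) != 2L) {
    stop("estimate_rolling_resistance: exactly two trials required", call. = FALSE)
  }
  decel <- vapply(trial_pair, function(tr) {
    stopifnot(inherits(tr, "imu_stream"))
    meta <- tr$meta
    if (is.null(meta$push_end_t) || is.null(meta$stop_t)) {
      stop("estimate_rolling_resistance: trial lacks push_end_t/stop_t metadata",
           call. = FALSE)
    }
    t1 <- meta$push_end_t + trim_s
    t2 <- meta$stop_t - trim_s
    if (t2 - t1 < 1.0) {
      stop("estimate_rolling_resistance: insufficient coast data after trimming",
           call. = FALSE)
    }
    sel <- tr$t >= t1 & tr$t <= t2
    v <- abs(spin_to_velocity(tr$gyro[, 3], geometry))[sel]
    abs(unname(stats::coef(stats::lm.fit(cbind(1, tr$t[sel]), v))[2]))
  }, numeric(1))
  mu_r <- mean(decel) / system$g
  attr(mu_r, "decel") <- decel
  mu_r
}

#' Force and power series from the velocity polynomial
#'
#' Newton's second law on the chair-athlete system:
#' `F_imu = mt * acc + F_rr + F_aero`, with `acc` the analytic derivative of
#' the fitted polynomial, rolling resistance
#' `F_rr = mt g (mu_r + kf pV^2)` and aerodynamic drag
#' `F_aero = 0.5 rho CdA pV^2`; power is `P_imu = F_imu * pV`.
#'
#' @param poly a [fit_velocity_polynomial()] result.
#' @param system a [system_properties()].
#' @param x evaluation grid in re-origined time; defaults to the fitting grid.
#' @return An object of class `force_power_series`: data frame `series` with
#'   columns `t`, `pV`, `acc`, `F_rr`, `F_aero`, `F_imu`, `P_imu`, and the
#'   window maxima `F_max`, `P_max`, `V_max` with their times.
#' @export
compute_force_power <- function(poly, system, x = NULL) {
  if (is.null(x)) x <- poly$x
  pV <- eval_velocity_polynomial(poly, x, 0L)
  acc <- eval_velocity_polynomial(poly, x, 1L)
  F_rr <- system$mt * system$g * (system$mu_r + system$kf * pV^2)
  F_aero <- 0.5 * system$rho * system$CdA * pV^2
  F_imu <- system$mt * acc + F_rr + F_aero
  P_imu <- F_imu * pV
  ser <- data.frame(t = x + poly$t0, x = x, pV = pV, acc = acc,
                    F_rr = F_rr, F_aero = F_aero, F_imu = F_imu, P_imu = P_imu)
  iF <- which.max(F_imu); iP <- which.max(P_imu); iV <- which.max(pV)
  structure(list(series = ser,
                 F_max = F_imu[iF], F_max_t = ser$t[iF],
                 P_max = P_imu[iP], P_max_t = ser$t[iP],
                 V_max = pV[iV], V_max_t = ser$t[iV]),
            class = "force_power_series")
}

#' Force-velocity profile
#'
#' Pairs each sample's modeled propulsive force with the fitted velocity,
#' one point per sample of the sprint window.
#'
#' @param fp a [compute_force_power()] result.
#' @return Data frame with columns `pV` (m/s) and `F_imu` (N).
#' @export
fv_profile <- function(fp) {
  data.frame(pV = fp$series$pV, F_imu = fp$series$F_imu)
}

#' Per-sprint scalar metrics
#'
#' @param poly fitted [fit_velocity_polynomial()] for the sprint window.
#' @param fp matching [compute_force_power()] result.
#' @param window the [detect_sprint_window()].
#' @param cycles the [segment_cycles()] result.
#' @param t full time vector of the sprint stream.
#' @return A one-row data frame: `F_max`, `V_max`, `P_max`, `V_mean`
#'   (track length over duration), `V_mean_start` (mean fitted velocity over
#'   the start window's time span), `sprint_time`, `n_cycles`.
#' @export
sprint_metrics <- function(poly, fp, window, cycles, t) {
  spans <- cycle_spans(cycles, window, t)
  xs <- spans$start - poly$t0
  xs_grid <- poly$x[poly$x >= xs[1] - 1e-9 & poly$x <= xs[2] + 1e-9]
  v_mean_start <- mean(eval_velocity_polynomial(poly, xs_grid, 0L))
  data.frame(F_max = fp$F_max, V_max = fp$V_max, P_max = fp$P_max,
             V_mean = window$track_length_m / window$duration_s,
             V_mean_start = v_mean_start,
             sprint_time = window$duration_s,
             n_cycles = cycles$n_cycles)
}
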