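#' Simulation configuration for a synthetic sprint session
#'
#' Defines the protocol and signal model of the synthetic-session generator:
#' 6 x 20 m sprints with 20 s recovery sampled at 128 Hz by default, a
#' saturating-exponential chair-velocity envelope `v_env(t) = v_max (1 -
#' exp(-t/tau))` carrying a rectified-sinusoid per-stroke ripple, controllable
#' left/right asymmetry (gain or phase mode, optionally enhanced over the first
#' three cycles), multiplicative per-sprint fatigue decay of the velocity
#' plateau, camber-induced yaw contamination of the wheel gyroscopes, and a
#' trunk flexion oscillation locked to the propulsion cycles.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @param n_sprints number of sprints in the session.
#' @param recovery_s recovery interval between sprints, seconds.
#' @param sample_rate_hz IMU sampling rate, Hz.
#' @param track_length_m sprint distance, meters.
#' @param athlete_mass_kg,chair_mass_kg masses, kg.
#' @param wheel_radius_m rear-wheel radius, meters.
#' @param camber_rad rear-wheel camber angle, radians.
#' @param track_width_m hub-to-hub distance between rear wheels, meters.
#' @param v_max_true asymptotic chair speed of the first sprint, m/s.
#' @param tau_s time constant of the velocity envelope, seconds.
#' @param stroke_freq_hz propulsion stroke frequency, Hz.
#' @param ripple_depth per-stroke velocity ripple amplitude as a fraction of
#'   the sprint's plateau speed (zero-mean within a stroke); the default 0.12
#'   gives a peak-to-trough fluctuation of about 0.5 m/s at 4.5 m/s, matching
#'   typical measured wheelchair sprint traces.
#' @param asymmetry_gain right/left wheel-speed ratio, >= 1 (gain mode).
#' @param asymmetry_mode `"gain"` (right wheel scaled) or `"phase"` (right
#'   wheel ripple shifted by `asymmetry_phase_frac` of a cycle at equal mean).
#' @param asymmetry_phase_frac phase-mode ripple shift, fraction of a cycle.
#' @param start_asym_boost multiplier on `(asymmetry_gain - 1)` during the
#'   first three stroke periods of each sprint; 1 disables the start
#'   enhancement.
#' @param fatigue_decay per-sprint multiplicative factor on the velocity
#'   plateau, in (0, 1].
#' @param mu_r_true rolling-resistance coefficient (unitless).
#' @param kf_true speed-on-friction coefficient, s^2/m^2.
#' @param CdA_true drag coefficient times frontal area, m^2.
#' @param trunk_amplitude_deg trunk flexion oscillation amplitude, degrees
#'   (per-cycle range of motion is twice this).
#' @param trunk_baseline_deg static trunk inclination offset, degrees.
#' @param static_hold_s still-sitting hold before each sprint, seconds (used
#'   by the static-offset correction).
#' @param noise_sd_gyro gyroscope white-noise standard deviation, rad/s.
#' @param yaw_oscillation_amp amplitude of a steering yaw wobble, rad/s,
#'   realized as an antisymmetric perturbation of the two wheel speeds.
#' @param yaw_oscillation_hz frequency of the yaw wobble, Hz.
#' @param decel_push_speed_m_s release speed of the coast-down trials, m/s.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sprints = 6L,
                       recovery_s = 20,
                       sample_rate_hz = 128,
                       track_length_m = 20,
                       athlete_mass_kg = 70,
                       chair_mass_kg = 15,
                       wheel_radius_m = 0.30,
                       camber_rad = 18 * pi / 180,
                       track_width_m = 0.60,
                       v_max_true = 4.5,
                       tau_s = 1.6,
                       stroke_freq_hz = 1.8,
                       ripple_depth = 0.12,
                       asymmetry_gain = 1.03,
                       asymmetry_mode = c("gain", "phase"),
                       asymmetry_phase_frac = 0.15,
                       start_asym_boost = 2,
                       fatigue_decay = 0.99,
                       mu_r_true = 0.012,
                       kf_true = 0,
                       CdA_true = 0.4,
                       trunk_amplitude_deg = 10,
                       trunk_baseline_deg = 5,
                       static_hold_s = 2,
                       noise_sd_gyro = 0.02,
                       yaw_oscillation_amp = 0,
                       yaw_oscillation_hz = 0.8,
                       decel_push_speed_m_s = 2.5) {
  cfg <- list(seed = as.integer(seed), n_sprints = as.integer(n_sprints),
              recovery_s = recovery_s, sample_rate_hz = sample_rate_hz,
              track_length_m = track_length_m,
              athlete_mass_kg = athlete_mass_kg, chair_mass_kg = chair_mass_kg,
              wheel_radius_m = wheel_radius_m, camber_rad = camber_rad,
              track_width_m = track_width_m, v_max_true = v_max_true,
              tau_s = tau_s, stroke_freq_hz = stroke_freq_hz,
              ripple_depth = ripple_depth, asymmetry_gain = asymmetry_gain,
              asymmetry_mode = match.arg(asymmetry_mode),
              asymmetry_phase_frac = asymmetry_phase_frac,
              start_asym_boost = start_asym_boost,
              fatigue_decay = fatigue_decay, mu_r_true = mu_r_true,
              kf_true = kf_true, CdA_true = CdA_true,
              trunk_amplitude_deg = trunk_amplitude_deg,
              trunk_baseline_deg = trunk_baseline_deg,
              static_hold_s = static_hold_s, noise_sd_gyro = noise_sd_gyro,
              yaw_oscillation_amp = yaw_oscillation_amp,
              yaw_oscillation_hz = yaw_oscillation_hz,
              decel_push_speed_m_s = decel_push_speed_m_s)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_positive(cfg$sample_rate_hz, "sample_rate_hz")
  check_positive(cfg$wheel_radius_m, "wheel_radius_m")
  check_positive(cfg$track_length_m, "track_length_m")
  check_positive(cfg$track_width_m, "track_width_m")
  check_positive(cfg$v_max_true, "v_max_true")
  check_positive(cfg$tau_s, "tau_s")
  check_positive(cfg$stroke_freq_hz, "stroke_freq_hz")
  check_positive(cfg$athlete_mass_kg, "athlete_mass_kg")
  check_positive(cfg$chair_mass_kg, "chair_mass_kg")
  check_nonneg(cfg$camber_rad, "camber_rad")
  check_nonneg(cfg$mu_r_true, "mu_r_true")
  check_nonneg(cfg$kf_true, "kf_true")
  check_nonneg(cfg$CdA_true, "CdA_true")
  check_nonneg(cfg$noise_sd_gyro, "noise_sd_gyro")
  check_nonneg(cfg$yaw_oscillation_amp, "yaw_oscillation_amp")
  check_nonneg(cfg$trunk_amplitude_deg, "trunk_amplitude_deg")
  if (cfg$n_sprints < 1L) {
    stop("invalid configuration: 'n_sprints' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$asymmetry_gain) || cfg$asymmetry_gain < 1) {
    stop("invalid configuration: 'asymmetry_gain' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$fatigue_decay) || cfg$fatigue_decay <= 0 || cfg$fatigue_decay > 1) {
    stop("invalid configuration: 'fatigue_decay' must be in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Wheel gyroscope signal from a linear-velocity trace
#'
#' Constructs the z-axis gyroscope signal a wheel-hub IMU would register for a
#' wheel of radius r rolling at linear speed v while the chassis yaws at rate
#' `yaw_rate`: because of the camber angle the sensor axis picks up a
#' projection of the chassis yaw, so
#' `omega_meas(t) = v(t)/r + yaw_rate(t) * sin(camber) + N(0, noise_sd)`.
#' This construction is the exact inverse contract of [correct_camber()].
#'
#' @param v linear-velocity series, m/s.
#' @param geometry a [wheel_geometry()].
#' @param yaw_rate chassis yaw-rate series (rad/s), recycled if scalar.
#' @param noise_sd white-noise standard deviation, rad/s.
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return Numeric series of measured wheel angular rate, rad/s.
#' @export
velocity_to_gyro <- function(v, geometry, yaw_rate = 0, noise_sd = 0, seed = NULL) {
  if (length(yaw_rate) == 1L) yaw_rate <- rep(yaw_rate, length(v))
  if (length(yaw_rate) != length(v)) {
    stop("velocity_to_gyro: v and yaw_rate must share length", call. = FALSE)
  }
  check_positive(geometry$radius_m, "radius_m")
  if (!is.null(seed)) set.seed(seed)
  omega <- v / geometry$radius_m + yaw_rate * sin(geometry$camber_rad)
  if (noise_sd > 0) omega <- omega + stats::rnorm(length(v), 0, noise_sd)
  omega
}

# internal: time for the envelope v_max*(1 - exp(-t/tau)) to cover `dist` m
envelope_time_to_distance <- function(v_max, tau, dist) {
  f <- function(T) v_max * (T - tau * (1 - exp(-T / tau))) - dist
  stats::uniroot(f, c(1e-3, dist / v_max + 20 * tau))$root
}

# internal: trunk flexion profile (degrees) on grid t, locked to cycle onsets.
# Baseline outside the cycling segment; within cycle k a full sine period, so
# the per-cycle range is exactly 2*amplitude.
trunk_flexion_profile <- function(t, cycle_times, amplitude_deg, baseline_deg) {
  theta <- rep(baseline_deg, length(t))
  k <- length(cycle_times)
  if (k >= 2L) {
    idx <- findInterval(t, cycle_times)
    inside <- idx >= 1L & idx < k
    u <- (t[inside] - cycle_times[idx[inside]]) /
      (cycle_times[idx[inside] + 1L] - cycle_times[idx[inside]])
    theta[inside] <- baseline_deg + amplitude_deg * sin(2 * pi * u)
  }
  theta
}

# internal: pitch-only unit quaternion (w, x, y, z) for flexion theta (deg)
flexion_to_quat <- function(theta_deg) {
  half <- theta_deg * pi / 360
  q <- cbind(cos(half), 0, sin(half), 0)
  stopifnot(all(abs(sqrt(rowSums(q^2)) - 1) < 1e-12))
  q
}

#' Synthetic trunk-orientation stream
#'
#' Encodes a trunk flexion oscillation as unit quaternions: a static hold at
#' the baseline inclination (for static-offset estimation) followed by one
#' full sine period of amplitude `amplitude_deg` per propulsion cycle, so the
#' true per-cycle trunk range of motion is exactly `2 * amplitude_deg`.
#'
#' @param cycle_times propulsion-cycle onset times, seconds (>= 2 values).
#' @param amplitude_deg flexion oscillation amplitude, degrees (>= 0).
#' @param baseline_deg static inclination offset, degrees.
#' @param sample_rate sampling rate, Hz.
#' @param static_hold_s duration of the still hold before the first cycle.
#' @return An [imu_stream()] with `sensor_id = "trunk"`; `meta$trm_true_deg`
#'   records the true per-cycle range and `meta$static_window` the hold span.
#' @export
generate_trunk_stream <- function(cycle_times, amplitude_deg, baseline_deg = 0,
                                  sample_rate = 128, static_hold_s = 2) {
  check_nonneg(amplitude_deg, "trunk_amplitude_deg")
  if (length(cycle_times) < 2L) {
    stop("generate_trunk_stream: need at least 2 cycle times", call. = FALSE)
  }
  t0 <- cycle_times[1] - static_hold_s
  t <- seq(t0, cycle_times[length(cycle_times)], by = 1 / sample_rate)
  theta <- trunk_flexion_profile(t, cycle_times, amplitude_deg, baseline_deg)
  quat <- flexion_to_quat(theta)
  gy <- c(0, diff(theta) * pi / 180) * sample_rate  # pitch rate, rad/s
  imu_stream(t = t, gyro = cbind(0, gy, 0), accel = NULL, quat = quat,
             sample_rate_hz = sample_rate, sensor_id = "trunk",
             meta = list(trm_true_deg = 2 * amplitude_deg,
                         static_window = c(t0, cycle_times[1]),
                         flexion_true_deg = theta))
}

#' Synthetic coast-down (deceleration) trial
#'
#' Emulates the rolling-resistance field test: the unoccupied chair is pushed
#' to `v_push`, released, coasts under `dv/dt = -g (mu_r + kf v^2) - (rho CdA /
#' (2 mt)) v^2` until it has covered the coast distance, and is then stopped.
#' Phase boundaries are recorded in the stream metadata (`push_end_t`,
#' `stop_t`). An optional track grade adds a direction-dependent gravity
#' component, which the two-direction averaging of the estimator cancels.
#'
#' @param mu_r_true true rolling-resistance coefficient.
#' @param kf_true true speed-on-friction coefficient, s^2/m^2.
#' @param system a [system_properties()] (mass, rho, CdA).
#' @param v_push release speed, m/s (the protocol uses roughly 2-2.8 m/s).
#' @param direction +1 or -1, travel direction along the track.
#' @param geometry a [wheel_geometry()] for the instrumented wheel.
#' @param sample_rate sampling rate, Hz.
#' @param coast_distance_m free-coast distance before the chair is stopped.
#' @param push_s duration of the push phase.
#' @param slope_grade track grade (rise/run); signed gravity bias
#'   `g * slope_grade * direction` is added to the coast deceleration.
#' @param noise_sd gyroscope noise, rad/s.
#' @param seed optional RNG seed.
#' @return An [imu_stream()] of the instrumented wheel.
#' @export
generate_decel_trial <- function(mu_r_true, kf_true = 0, system, v_push = 2.5,
                                 direction = 1, geometry,
                                 sample_rate = 128, coast_distance_m = 5,
                                 push_s = 1.5, slope_grade = 0,
                                 noise_sd = 0, seed = NULL) {
  if (v_push <= 0) {
    stop("invalid configuration: 'v_push' must be positive", call. = FALSE)
  }
  check_nonneg(mu_r_true, "mu_r_true")
  if (!is.null(seed)) set.seed(seed)
  g <- system$g
  a <- g * (mu_r_true + slope_grade * direction)
  b <- g * kf_true + 0.5 * system$rho * system$CdA / system$mt
  if (a < 0) stop("generate_decel_trial: grade exceeds rolling resistance", call. = FALSE)

  dt <- 1 / sample_rate
  # coast speed profile, closed form of dv/dt = -a - b v^2
  coast_v <- function(tc) {
    if (b == 0 && a == 0) rep(v_push, length(tc))
    else if (b == 0) pmax(v_push - a * tc, 0)
    else if (a == 0) v_push / (1 + b * v_push * tc)
    else {
      k <- sqrt(a * b)
      phi <- atan(v_push * sqrt(b / a))
      pmax(sqrt(a / b) * tan(pmax(phi - k * tc, 0)), 0)
    }
  }
  # coast until coast_distance_m covered (or speed nearly gone)
  tc <- seq(0, 60, by = dt)
  vc <- coast_v(tc)
  dist <- c(0, cumsum((vc[-1] + vc[-length(vc)]) / 2 * dt))
  n_coast <- which(dist >= coast_distance_m | vc <= 0.15)[1]
  if (is.na(n_coast)) n_coast <- length(tc)
  vc <- vc[seq_len(n_coast)]

  t_push <- seq(0, push_s, by = dt)
  v_phase_push <- v_push * (1 - cos(pi * t_push / push_s)) / 2
  v_stop <- vc[n_coast] * seq(1, 0, length.out = round(0.3 * sample_rate))
  v <- c(v_phase_push, vc[-1], v_stop)
  t <- seq(0, by = dt, length.out = length(v))
  push_end_t <- push_s
  stop_t <- t[length(t_push) + n_coast - 1L]

  gz <- direction * v / geometry$radius_m
  if (noise_sd > 0) gz <- gz + stats::rnorm(length(gz), 0, noise_sd)
  imu_stream(t = t, gyro = cbind(0, 0, gz), accel = NULL, quat = NULL,
             sample_rate_hz = sample_rate, sensor_id = "left_wheel",
             meta = list(push_end_t = push_end_t, stop_t = stop_t,
                         direction = direction, v_true = v))
}

#' Generate a complete synthetic sprint session
#'
#' Produces `n_sprints` sets of four IMU streams (left wheel, right wheel,
#' frame, trunk) plus two coast-down trials, with full ground truth for
#' parameter-recovery validation. Each sprint starts from rest after a still
#' hold, accelerates along a saturating-exponential envelope whose plateau
#' decays by `fatigue_decay` per sprint, and carries a per-stroke velocity
#' ripple whose minima define the propulsion cycles. Wheel gyroscopes are
#' contaminated by camber-projected chassis yaw (always consistent with the
#' differential wheel speed) and white noise. The frame stream receives
#' additive drift and vibration and is not used by the analysis.
#'
#' @param config a [sim_config()].
#' @return An object of class `synthetic_session`: `streams` (per-sprint list
#'   of named [imu_stream()]s), `decel_trials` (two trials, opposite
#'   directions), `ground_truth`, and the generating `config`.
#' @export
generate_session <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  dt <- 1 / fs
  f <- config$stroke_freq_hz
  geom_L <- wheel_geometry(config$wheel_radius_m, config$camber_rad, "left",
                           config$track_width_m)
  geom_R <- wheel_geometry(config$wheel_radius_m, config$camber_rad, "right",
                           config$track_width_m)

  streams <- vector("list", config$n_sprints)
  gt <- list(mu_r = config$mu_r_true, kf = config$kf_true, CdA = config$CdA_true,
             sprints = vector("list", config$n_sprints))

  for (s in seq_len(config$n_sprints)) {
    v_max_s <- config$v_max_true * config$fatigue_decay^(s - 1)
    T_drive <- envelope_time_to_distance(v_max_s, config$tau_s,
                                         config$track_length_m * 1.08) + 0.5
    lead <- config$static_hold_s
    t <- seq(0, lead + T_drive, by = dt)
    td <- pmax(t - lead, 0)            # time since drive onset
    env <- ifelse(t >= lead, v_max_s * (1 - exp(-td / config$tau_s)), 0)

    # per-stroke ripple: zero-mean within a stroke, ramped in over the first
    # stroke so speed stays non-negative; the first strokes carry deeper dips
    # (hands off the rim from near-rest), decaying to the steady amplitude
    amp <- config$ripple_depth * v_max_s *
      (1 + 0.8 * exp(-td * f / 1.5)) * pmin(td * f, 1) * (t >= lead)
    ripple <- function(phase_frac) {
      amp * (abs(sin(pi * f * td - pi * phase_frac)) - 2 / pi)
    }
    v_chair <- env + ripple(0)

    if (config$asymmetry_mode == "gain") {
      g_eff <- ifelse(td < 3 / f,
                      1 + (config$asymmetry_gain - 1) * config$start_asym_boost,
                      config$asymmetry_gain)
      v_L <- v_chair * 2 / (1 + g_eff)
      v_R <- v_chair * 2 * g_eff / (1 + g_eff)
    } else {
      v_L <- v_chair
      v_R <- env + ripple(config$asymmetry_phase_frac)
    }
    if (config$yaw_oscillation_amp > 0) {
      wob <- config$yaw_oscillation_amp *
        sin(2 * pi * config$yaw_oscillation_hz * td) * (t >= lead)
      v_L <- v_L - wob * config$track_width_m / 2
      v_R <- v_R + wob * config$track_width_m / 2
    }
    yaw <- (v_R - v_L) / config$track_width_m

    gz_L <- velocity_to_gyro(v_L, geom_L, yaw, config$noise_sd_gyro)
    gz_R <- velocity_to_gyro(v_R, geom_R, yaw, config$noise_sd_gyro)
    n <- length(t)
    wheel_noise <- function() matrix(stats::rnorm(2 * n, 0, config$noise_sd_gyro), n, 2)

    # frame accelerometer: true forward accel + drift + vibration (unused by
    # the pipeline; emulates why frame integration is unreliable)
    acc_true <- c(0, diff((v_L + v_R) / 2)) * fs
    drift <- cumsum(stats::rnorm(n, 0, 0.02 / sqrt(fs)))
    vib <- 0.4 * sin(2 * pi * 20 * t) + stats::rnorm(n, 0, 0.2)
    frame_acc <- cbind(acc_true + drift + vib, stats::rnorm(n, 0, 0.2),
                       9.81 + stats::rnorm(n, 0, 0.2))

    # true cycle onsets: ripple minima at td = k/f, within the drive phase
    k_max <- floor((T_drive - 1e-9) * f)
    cycle_times_all <- lead + seq_len(k_max) / f

    theta <- trunk_flexion_profile(t, cycle_times_all, config$trunk_amplitude_deg,
                                   config$trunk_baseline_deg)
    quat <- flexion_to_quat(theta)
    trunk_gy <- c(0, diff(theta) * pi / 180) * fs

    streams[[s]] <- list(
      left_wheel = imu_stream(t, cbind(wheel_noise(), gz_L), NULL, NULL, fs, "left_wheel"),
      right_wheel = imu_stream(t, cbind(wheel_noise(), gz_R), NULL, NULL, fs, "right_wheel"),
      frame = imu_stream(t, cbind(matrix(stats::rnorm(2 * n, 0, 0.05), n, 2),
                                  yaw + stats::rnorm(n, 0, 0.05)),
                         frame_acc, NULL, fs, "frame"),
      trunk = imu_stream(t, cbind(0, trunk_gy, 0), NULL, quat, fs, "trunk",
                         meta = list(static_window = c(0, lead)))
    )

    # ground truth from the noise-free traces, by the pipeline's definitions
    v_mean_true <- (v_L + v_R) / 2
    win <- detect_sprint_window(v_L, v_R, fs, config$track_length_m, t = t)
    cyc_t <- cycle_times_all[cycle_times_all >= win$start_t &
                               cycle_times_all <= win$end_t]
    isi_true <- if (length(cyc_t) >= 8L) {
      spans <- list(start = c(cyc_t[1], cyc_t[4]),
                    middle = c(cyc_t[4], cyc_t[length(cyc_t) - 4L]),
                    end = c(cyc_t[length(cyc_t) - 4L], win$end_t),
                    overall = c(win$start_t, win$end_t))
      lapply(spans, function(sp) {
        if (diff(sp) <= 0) NA_real_
        else compute_isi(v_R, v_L, t, sp[1], sp[2])
      })
    } else NULL

    gt$sprints[[s]] <- list(
      t = t, v_left = v_L, v_right = v_R, v_envelope = env,
      v_max = max(env[seq(win$start_idx, win$end_idx)]),
      sprint_time = win$duration_s, window = win,
      cycle_times = cyc_t, n_cycles = length(cyc_t),
      isi = isi_true,
      trm_deg = 2 * config$trunk_amplitude_deg,
      flexion_true_deg = theta
    )
  }

  system <- system_properties(mt = config$athlete_mass_kg + config$chair_mass_kg,
                              mu_r = config$mu_r_true, kf = config$kf_true,
                              CdA = config$CdA_true)
  decel <- list(
    generate_decel_trial(config$mu_r_true, config$kf_true, system,
                         v_push = config$decel_push_speed_m_s, direction = 1,
                         geometry = geom_L, sample_rate = fs,
                         noise_sd = config$noise_sd_gyro),
    generate_decel_trial(config$mu_r_true, config$kf_true, system,
                         v_push = config$decel_push_speed_m_s, direction = -1,
                         geometry = geom_L, sample_rate = fs,
                         noise_sd = config$noise_sd_gyro)
  )

  structure(list(streams = streams, decel_trials = decel,
                 ground_truth = gt, config = config),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %d sprints @ %g Hz, %g m track, seed %d\n",
              x$config$n_sprints, x$config$sample_rate_hz,
              x$config$track_length_m, x$config$seed))
  invisible(x)
}
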