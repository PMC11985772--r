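#' Wheel geometry
#'
#' @param radius_m wheel radius, meters (> 0).
#' @param camber_rad camber angle, radians (in `[0, pi/4)`); sport chairs use
#'   roughly 15-20 degrees.
#' @param side `"left"` or `"right"`.
#' @param track_width_m hub-to-hub distance, meters.
#' @return An object of class `wheel_geometry`.
#' @export
wheel_geometry <- function(radius_m, camber_rad = 0, side = c("left", "right"),
                           track_width_m = 0.6) {
  check_positive(radius_m, "radius_m")
  check_positive(track_width_m, "track_width_m")
  if (camber_rad < 0 || camber_rad >= pi / 4) {
    stop("invalid configuration: 'camber_rad' must be in [0, pi/4)", call. = FALSE)
  }
  structure(list(radius_m = radius_m, camber_rad = camber_rad,
                 side = match.arg(side), track_width_m = track_width_m),
            class = "wheel_geometry")
}

#' Camber correction of wheel gyroscope signals
#'
#' A cambered wheel's gyroscope measures the wheel spin plus a projection of
#' the chassis yaw rate: `omega_meas = omega_spin + Omega * sin(camber)`. With
#' the chassis yaw tied to the differential wheel speed,
#' `Omega = (r_R * omega_R - r_L * omega_L) / track_width`, the two measured
#' signals define a constant 2x2 linear system in the two true spin rates,
#' solved here per sample. With zero camber the output equals the input.
#'
#' @param gyro_left,gyro_right measured wheel angular-rate series, rad/s.
#' @param geometry_left,geometry_right [wheel_geometry()] of each wheel; they
#'   must agree on `track_width_m`.
#' @return A list with `spin_left`, `spin_right` (rad/s) and the implied
#'   chassis `yaw` series.
#' @export
correct_camber <- function(gyro_left, gyro_right, geometry_left, geometry_right) {
  if (length(gyro_left) != length(gyro_right)) {
    stop("correct_camber: left/right series must share length", call. = FALSE)
  }
  w <- geometry_left$track_width_m
  if (abs(w - geometry_right$track_width_m) > 1e-12) {
    stop("correct_camber: geometries disagree on track_width_m", call. = FALSE)
  }
  sL <- sin(geometry_left$camber_rad)
  sR <- sin(geometry_right$camber_rad)
  rL <- geometry_left$radius_m
  rR <- geometry_right$radius_m
  # [m_L; m_R] = M [w_L; w_R]
  M <- matrix(c(1 - sL * rL / w, -sR * rL / w,
                sL * rR / w, 1 + sR * rR / w), 2, 2)
  det_M <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(det_M) < 1e-8) {
    stop(sprintf(
      "correct_camber: singular geometry (det = %.3e); camber/radius/track_width make wheel spin unidentifiable",
      det_M), call. = FALSE)
  }
  inv <- matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det_M
  spin_L <- inv[1, 1] * gyro_left + inv[1, 2] * gyro_right
  spin_R <- inv[2, 1] * gyro_left + inv[2, 2] * gyro_right
  list(spin_left = spin_L, spin_right = spin_R,
       yaw = (rR * spin_R - rL * spin_L) / w)
}

#' Wheel spin to linear velocity
#'
#' @param spin wheel spin series, rad/s.
#' @param geometry a [wheel_geometry()].
#' @return Linear-velocity series `spin * radius_m`, m/s.
#' @export
spin_to_velocity <- function(spin, geometry) {
  check_positive(geometry$radius_m, "radius_m")
  spin * geometry$radius_m
}

#' Optional zero-phase low-pass filter
#'
#' Disabled by default (the pipeline applies no pre-filtering); when a cutoff
#' is given, a 2nd-order Butterworth filter is applied forward and backward.
#'
#' @param x signal series.
#' @param sample_rate_hz sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz, or `NULL` for no filtering.
#' @return The (possibly filtered) series.
#' @export
lowpass_filter <- function(x, sample_rate_hz, cutoff_hz = NULL) {
  if (is.null(cutoff_hz)) return(x)
  bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect the sprint window from bilateral wheel velocity
#'
#' The sprint start is the first sample at which the average of the two wheel
#' speeds exceeds 0.06 m/s; the end is the first sample at which the
#' trapezoidal integral of the average speed from the start reaches the track
#' length.
#'
#' @param v_left,v_right wheel linear-velocity series, m/s.
#' @param sample_rate sampling rate, Hz.
#' @param track_length_m sprint distance, meters.
#' @param t optional time vector; defaults to `(0:(n-1)) / sample_rate`.
#' @param threshold start-detection speed threshold, m/s.
#' @return An object of class `sprint_window` with 1-based inclusive sample
#'   indices `start_idx`, `end_idx`, times `start_t`, `end_t`, `duration_s`,
#'   the integrated `distance_m`, and the nominal `track_length_m`.
#' @export
detect_sprint_window <- function(v_left, v_right, sample_rate, track_length_m,
                                 t = NULL, threshold = 0.06) {
  if (length(v_left) != length(v_right)) {
    stop("detect_sprint_window: series must share length", call. = FALSE)
  }
  v <- (v_left + v_right) / 2
  n <- length(v)
  if (is.null(t)) t <- (seq_len(n) - 1L) / sample_rate
  start_idx <- which(v > threshold)[1]
  if (is.na(start_idx)) {
    stop("detect_sprint_window: no start detected (threshold never crossed)",
         call. = FALSE)
  }
  # at-rest precondition: the (up to) 0.5 s preceding the crossing
  pre <- seq(max(1L, start_idx - round(0.5 * sample_rate)), start_idx - 1L)
  if (start_idx == 1L || mean(v[pre]) > threshold) {
    stop("detect_sprint_window: chair not at rest before the detected start",
         call. = FALSE)
  }
  seg <- seq(start_idx, n)
  dist <- pracma::cumtrapz(t[seg], v[seg])[, 1]
  rel_end <- which(dist >= track_length_m)[1]
  if (is.na(rel_end)) {
    stop("detect_sprint_window: sprint incomplete (distance never reached)",
         call. = FALSE)
  }
  end_idx <- start_idx + rel_end - 1L
  structure(list(start_idx = start_idx, end_idx = end_idx,
                 start_t = t[start_idx], end_t = t[end_idx],
                 duration_s = t[end_idx] - t[start_idx],
                 distance_m = dist[rel_end],
                 track_length_m = track_length_m),
            class = "sprint_window")
}

# internal: local minima of v with prominence and spacing guards
find_cycle_minima <- function(v, sample_rate, min_spacing_s, min_prom_frac) {
  n <- length(v)
  cand <- which(diff(sign(diff(v))) > 0) + 1L    # strict local minima
  if (length(cand) == 0L) return(integer(0))
  rng <- max(v) - min(v)
  prom_ok <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    lo <- if (j == 1L) 1L else cand[j - 1L]
    hi <- if (j == length(cand)) n else cand[j + 1L]
    prom <- min(max(v[lo:i]), max(v[i:hi])) - v[i]
    prom >= min_prom_frac * rng
  }, logical(1))
  cand <- cand[prom_ok]
  # enforce minimum spacing, keeping the deeper minimum of close pairs
  spacing <- min_spacing_s * sample_rate
  repeat {
    if (length(cand) < 2L) break
    gaps <- diff(cand)
    close <- which(gaps < spacing)
    if (length(close) == 0L) break
    j <- close[1]
    drop <- if (v[cand[j]] <= v[cand[j + 1L]]) j + 1L else j
    cand <- cand[-drop]
  }
  cand
}

#' Segment propulsion cycles within a sprint window
#'
#' Cycle onsets are local minima of the average wheel velocity, guarded by a
#' minimum spacing and a minimum prominence relative to the window's velocity
#' range. Cycles are partitioned into the start window (first 3 cycles), the
#' end window (last 5 cycles) and the middle window (the remainder, possibly
#' empty when exactly 8 cycles are present).
#'
#' @param v_mean average wheel velocity restricted to the sprint window, m/s.
#' @param window the [detect_sprint_window()] result (used for time bounds).
#' @param sample_rate sampling rate, Hz.
#' @param min_spacing_s minimum time between cycle onsets, seconds.
#' @param min_prominence_frac minimum prominence as a fraction of the window's
#'   velocity range.
#' @return An object of class `cycle_segmentation`: `boundaries` (onset
#'   indices, 1-based within the window), `n_cycles`, and index vectors
#'   `window_start`, `window_middle`, `window_end` over cycles.
#' @export
segment_cycles <- function(v_mean, window, sample_rate,
                           min_spacing_s = 0.25, min_prominence_frac = 0.02) {
  boundaries <- find_cycle_minima(v_mean, sample_rate,
                                  min_spacing_s, min_prominence_frac)
  n_cycles <- length(boundaries)
  if (n_cycles < 8L) {
    stop(sprintf(
      "segment_cycles: insufficient cycles for window partition (%d detected, need >= 8)",
      n_cycles), call. = FALSE)
  }
  structure(list(boundaries = boundaries, n_cycles = n_cycles,
                 window_start = 1:3,
                 window_middle = if (n_cycles > 8L) 4:(n_cycles - 5L) else integer(0),
                 window_end = (n_cycles - 4L):n_cycles),
            class = "cycle_segmentation")
}

#' Time spans of the start/middle/end cycle windows
#'
#' @param cycles a [segment_cycles()] result.
#' @param window the corresponding [detect_sprint_window()].
#' @param t full time vector of the stream the window indexes into.
#' @return Named list of `c(t1, t2)` spans: `start`, `middle` (NULL when
#'   empty), `end`, `overall`, plus per-cycle spans in `per_cycle`.
#' @export
cycle_spans <- function(cycles, window, t) {
  tb <- t[window$start_idx + cycles$boundaries - 1L]
  end_t <- window$end_t
  onsets <- c(tb, end_t)
  per_cycle <- lapply(seq_len(cycles$n_cycles),
                      function(i) c(onsets[i], onsets[i + 1L]))
  mid <- if (length(cycles$window_middle) > 0L) {
    c(tb[4L], tb[cycles$n_cycles - 4L])
  } else NULL
  list(start = c(tb[1L], tb[4L]),
       middle = mid,
       end = c(tb[cycles$n_cycles - 4L], end_t),
       overall = c(window$start_t, end_t),
       per_cycle = per_cycle)
}
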