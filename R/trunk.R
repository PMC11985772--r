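# Trunk kinematics: quaternion orientation -> y-z-x Euler flexion angle,
# static-offset correction, and per-cycle trunk range of motion (TRM).

# internal: rotation matrices (n x 3 x 3) from unit quaternions (n x 4, wxyz)
quat_to_rotmat <- function(quat) {
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]
  R <- array(0, c(length(w), 3, 3))
  R[, 1, 1] <- 1 - 2 * (y^2 + z^2)
  R[, 1, 2] <- 2 * (x * y - w * z)
  R[, 1, 3] <- 2 * (x * z + w * y)
  R[, 2, 1] <- 2 * (x * y + w * z)
  R[, 2, 2] <- 1 - 2 * (x^2 + z^2)
  R[, 2, 3] <- 2 * (y * z - w * x)
  R[, 3, 1] <- 2 * (x * z - w * y)
  R[, 3, 2] <- 2 * (y * z + w * x)
  R[, 3, 3] <- 1 - 2 * (x^2 + y^2)
  R
}

#' Trunk flexion angle from quaternion orientation
#'
#' Decomposes each orientation's rotation matrix in an intrinsic y-z-x Euler
#' sequence `R = Ry(a) Rz(b) Rx(c)` and returns the first angle `a` — the
#' rotation about the mediolateral (pitch) axis, i.e. anteroposterior trunk
#' flexion relative to the global earth frame — in degrees, unwrapped to
#' avoid +/-180 degree jumps. For this decomposition
#' `b = asin(R[2,1])`, `a = atan2(-R[3,1], R[1,1])`, `c = atan2(-R[2,3], R[2,2])`.
#'
#' @param quat n x 4 matrix of quaternions (w, x, y, z); normalized internally
#'   when within 1e-3 of unit norm.
#' @return Flexion angle series in degrees, with attribute `"gimbal"` — a
#'   logical vector flagging samples whose middle angle is within 0.5 degrees
#'   of +/-90 degrees (where the decomposition degenerates).
#' @export
quaternion_to_flexion <- function(quat) {
  quat <- as.matrix(quat)
  if (ncol(quat) != 4L) stop("quaternion_to_flexion: quat must be n x 4", call. = FALSE)
  norms <- sqrt(rowSums(quat^2))
  if (any(abs(norms - 1) > 1e-3)) {
    stop("quaternion_to_flexion: quaternions not unit norm (within 1e-3)",
         call. = FALSE)
  }
  quat <- quat / norms
  R <- quat_to_rotmat(quat)
  sb <- pmin(pmax(R[, 2, 1], -1), 1)
  b <- asin(sb)
  a <- atan2(-R[, 3, 1], R[, 1, 1])
  gimbal <- abs(abs(b) - pi / 2) < 0.5 * pi / 180
  if (any(gimbal)) {
    warning(sprintf(
      "quaternion_to_flexion: %d sample(s) near gimbal lock (middle angle within 0.5 deg of +/-90 deg)",
      sum(gimbal)))
  }
  flex <- as.numeric(signal::unwrap(a)) * 180 / pi
  attr(flex, "gimbal") <- gimbal
  flex
}

#' Static-offset correction of the flexion angle
#'
#' Subtracts the mean flexion over a still-sitting window preceding the
#' sprint, formalizing the experimenter's visual offset assessment. The
#' athlete must actually be still: a flexion range above 2 degrees within the
#' static window is rejected.
#'
#' @param flexion flexion series, degrees.
#' @param t time series, seconds.
#' @param static_window `c(t_start, t_end)` of the still hold, seconds.
#' @return Offset-corrected flexion series; the subtracted offset (degrees)
#'   is attached as attribute `"offset_deg"`.
#' @export
apply_static_offset <- function(flexion, t, static_window) {
  sel <- t >= static_window[1] & t <= static_window[2]
  if (sum(sel) < 2L) {
    stop("apply_static_offset: static window contains fewer than 2 samples",
         call. = FALSE)
  }
  w <- flexion[sel]
  if (max(w) - min(w) > 2) {
    stop("apply_static_offset: athlete not still (flexion range > 2 deg in static window)",
         call. = FALSE)
  }
  offset <- mean(w)
  out <- flexion - offset
  attr(out, "offset_deg") <- offset
  out
}

#' Trunk range of motion per cycle and per window
#'
#' TRM of a propulsion cycle is the difference between the maximum and the
#' minimum trunk flexion within that cycle; window values are the mean TRM
#' over the window's cycles (start = first 3, end = last 5, middle = rest).
#'
#' @param flexion flexion series, degrees, on the full stream grid.
#' @param t full time vector, seconds.
#' @param cycles a [segment_cycles()] result.
#' @param window the matching [detect_sprint_window()].
#' @return A list of class `trunk_series`: `trm_per_cycle` (degrees),
#'   `trm_start`, `trm_middle` (NA when empty), `trm_end`, `trm_overall`.
#' @export
compute_trm <- function(flexion, t, cycles, window) {
  spans <- cycle_spans(cycles, window, t)
  trm <- vapply(spans$per_cycle, function(sp) {
    sel <- t >= sp[1] & t <= sp[2]
    diff(range(flexion[sel]))
  }, numeric(1))
  win_mean <- function(idx) if (length(idx) == 0L) NA_real_ else mean(trm[idx])
  structure(list(trm_per_cycle = trm,
                 trm_start = win_mean(cycles$window_start),
                 trm_middle = win_mean(cycles$window_middle),
                 trm_end = win_mean(cycles$window_end),
                 trm_overall = mean(trm)),
            class = "trunk_series")
}
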