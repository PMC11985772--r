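# Independent oracles used across the suite.

# quaternion product (w, x, y, z), independent of the package's rotation code
quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_axis <- function(angle_rad, axis) {
  u <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  c(cos(angle_rad / 2), sin(angle_rad / 2) * u)
}

# intrinsic y-z-x composition: R = Ry(a) Rz(b) Rx(c)
quat_yzx <- function(a, b, c) {
  quat_mult(quat_mult(quat_axis(a, "y"), quat_axis(b, "z")), quat_axis(c, "x"))
}

# trapezoidal ISI at an arbitrary rate from closed-form signal functions
isi_oracle <- function(R_fun, L_fun, t1, t2, rate) {
  t <- seq(t1, t2, by = 1 / rate)
  R <- R_fun(t); L <- L_fun(t)
  pracma::trapz(t, abs(R - L)) /
    (pracma::trapz(t, abs(R)) + pracma::trapz(t, abs(L)))
}

# left/right velocity pair consistent with a prescribed chassis yaw:
# yaw is realized as differential wheel speed over the track width
consistent_wheel_pair <- function(v_mean, yaw, track_width) {
  list(v_left = v_mean - yaw * track_width / 2,
       v_right = v_mean + yaw * track_width / 2)
}
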