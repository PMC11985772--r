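#' IMU stream container
#'
#' A uniformly sampled record from one inertial measurement unit: 3-axis
#' gyroscope (rad/s), 3-axis accelerometer (m/s^2) and, where the sensor
#' provides it, a unit quaternion orientation (w, x, y, z). This is the raw
#' input of every stage of the pipeline; one stream per sensor per trial.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing on a
#'   uniform grid (tolerance 1e-6 s).
#' @param gyro n x 3 numeric matrix of angular rates in rad/s (columns x, y, z).
#' @param accel n x 3 numeric matrix of accelerations in m/s^2, or `NULL`.
#' @param quat n x 4 numeric matrix of unit quaternions (w, x, y, z), or `NULL`
#'   (wheel sensors do not need orientation).
#' @param sample_rate_hz sampling rate in Hz.
#' @param sensor_id one of `"left_wheel"`, `"right_wheel"`, `"frame"`, `"trunk"`.
#' @param meta named list of trial metadata (e.g. coast-down phase timestamps
#'   `push_end_t` and `stop_t`).
#'
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(t, gyro, accel = NULL, quat = NULL,
                       sample_rate_hz, sensor_id = "frame", meta = list()) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("imu_stream: need at least 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("imu_stream: t must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6) {
    stop("imu_stream: t must be a uniform grid (within 1e-6 s)", call. = FALSE)
  }
  gyro <- as.matrix(gyro)
  dimnames(gyro) <- NULL
  if (nrow(gyro) != n || ncol(gyro) != 3L) {
    stop("imu_stream: gyro must be an n x 3 matrix", call. = FALSE)
  }
  if (!is.null(accel)) {
    accel <- as.matrix(accel)
    dimnames(accel) <- NULL
    if (nrow(accel) != n || ncol(accel) != 3L) {
      stop("imu_stream: accel must be an n x 3 matrix", call. = FALSE)
    }
  }
  if (!is.null(quat)) {
    quat <- as.matrix(quat)
    dimnames(quat) <- NULL
    if (nrow(quat) != n || ncol(quat) != 4L) {
      stop("imu_stream: quat must be an n x 4 matrix", call. = FALSE)
    }
    norms <- sqrt(rowSums(quat^2))
    if (any(abs(norms - 1) > 1e-6)) {
      stop("imu_stream: quaternions must be unit norm within 1e-6", call. = FALSE)
    }
  }
  sensor_id <- match.arg(sensor_id, c("left_wheel", "right_wheel", "frame", "trunk"))
  structure(
    list(t = t, gyro = gyro, accel = accel, quat = quat,
         sample_rate_hz = sample_rate_hz, sensor_id = sensor_id, meta = meta),
    class = "imu_stream"
  )
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> sensor=%s  n=%d  rate=%g Hz  span=[%.3f, %.3f] s  quat=%s\n",
              x$sensor_id, length(x$t), x$sample_rate_hz,
              x$t[1], x$t[length(x$t)], if (is.null(x$quat)) "no" else "yes"))
  invisible(x)
}

#' Write an IMU stream to CSV
#'
#' Column dialect `t,gx,gy,gz,ax,ay,az,qw,qx,qy,qz` in SI units; quaternion
#' columns are omitted when the stream carries no orientation.
#'
#' @param stream an [imu_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(inherits(stream, "imu_stream"))
  df <- data.frame(t = stream$t,
                   gx = stream$gyro[, 1], gy = stream$gyro[, 2], gz = stream$gyro[, 3])
  if (!is.null(stream$accel)) {
    df$ax <- stream$accel[, 1]; df$ay <- stream$accel[, 2]; df$az <- stream$accel[, 3]
  } else {
    df$ax <- 0; df$ay <- 0; df$az <- 0
  }
  if (!is.null(stream$quat)) {
    df$qw <- stream$quat[, 1]; df$qx <- stream$quat[, 2]
    df$qy <- stream$quat[, 3]; df$qz <- stream$quat[, 4]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU stream from CSV
#'
#' @param path CSV file in the `t,gx,gy,gz,ax,ay,az[,qw,qx,qy,qz]` dialect.
#' @param sensor_id sensor label to attach.
#' @param sample_rate_hz sampling rate; inferred from the time column when `NULL`.
#' @param meta named list of metadata to attach.
#' @return An [imu_stream()].
#' @export
read_imu_csv <- function(path, sensor_id = "frame", sample_rate_hz = NULL,
                         meta = list()) {
  df <- utils::read.csv(path)
  need <- c("t", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop("read_imu_csv: file lacks required columns t,gx,gy,gz", call. = FALSE)
  }
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / stats::median(diff(df$t))
  quat <- NULL
  if (all(c("qw", "qx", "qy", "qz") %in% names(df))) {
    quat <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  }
  accel <- NULL
  if (all(c("ax", "ay", "az") %in% names(df))) {
    accel <- as.matrix(df[, c("ax", "ay", "az")])
  }
  imu_stream(t = df$t, gyro = as.matrix(df[, c("gx", "gy", "gz")]),
             accel = accel, quat = quat,
             sample_rate_hz = sample_rate_hz, sensor_id = sensor_id, meta = meta)
}
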