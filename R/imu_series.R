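#' Uniformly sampled 9-axis IMU record
#'
#' Container for a synchronised gyroscope / accelerometer / magnetometer
#' record sampled on a uniform grid. All signals are expressed in the sensor
#' frame: gyroscope in rad/s, accelerometer in m/s^2, magnetometer in any
#' consistent unit (only its direction and relative magnitude are used).
#'
#' @param gyro,accel,mag Numeric matrices with one row per sample and columns
#'   x, y, z.
#' @param dt Sampling interval, seconds.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `imu_series` with elements `t`, `gyro`, `accel`,
#'   `mag`, `dt`, `n`.
#' @export
imu_series <- function(gyro, accel, mag, dt, t0 = 0) {
  gyro <- as_xyz_matrix(gyro, "gyro")
  accel <- as_xyz_matrix(accel, "accel")
  mag <- as_xyz_matrix(mag, "mag")
  n <- nrow(gyro)
  if (n < 2) stop("an imu_series needs at least 2 samples", call. = FALSE)
  if (nrow(accel) != n || nrow(mag) != n) {
    stop("gyro, accel and mag must have the same number of rows", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  stop_if_not_finite(gyro, "gyro")
  stop_if_not_finite(accel, "accel")
  stop_if_not_finite(mag, "mag")
  structure(
    list(t = t0 + dt * (seq_len(n) - 1),
         gyro = gyro, accel = accel, mag = mag, dt = dt, n = n),
    class = "imu_series"
  )
}

as_xyz_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3) stop(sprintf("%s must have 3 columns (x, y, z)", what),
                         call. = FALSE)
  colnames(m) <- c("x", "y", "z")
  storage.mode(m) <- "double"
  m
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %g Hz (%.2f s)\n",
              x$n, 1 / x$dt, x$n * x$dt))
  cat(sprintf("  gyro  rms: %.3f rad/s   accel rms: %.3f m/s^2\n",
              sqrt(mean(x$gyro^2)), sqrt(mean(x$accel^2))))
  invisible(x)
}

#' Extract a time window from an IMU record
#'
#' @param imu An [imu_series()].
#' @param from,to Window limits in seconds (inclusive, on the record's clock).
#' @return An `imu_series` restricted to the window.
#' @export
imu_window <- function(imu, from = -Inf, to = Inf) {
  keep <- imu$t >= from & imu$t <= to
  if (sum(keep) < 2) stop("window retains fewer than 2 samples", call. = FALSE)
  imu_series(imu$gyro[keep, , drop = FALSE], imu$accel[keep, , drop = FALSE],
             imu$mag[keep, , drop = FALSE], imu$dt, t0 = imu$t[keep][1])
}
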