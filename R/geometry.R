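#' Sensor mounting geometry
#'
#' Position of the sensor relative to the knee-joint centre, expressed in the
#' sensor coordinate frame (x lateral, y anterior, z along the shank). The
#' defaults correspond to a sensor strapped to the mid-shank: `rx = 0`,
#' `ry = -0.05` m, and `rz` near the middle of the -0.215 to -0.190 m range
#' observed across adult shank lengths.
#'
#' @param rx,ry,rz Components of the knee-to-sensor position vector, metres.
#' @return An object of class `sensor_geometry` with element `r`, a named
#'   3-vector in metres.
#' @examples
#' sensor_geometry()
#' sensor_geometry(rz = -0.21)
#' @export
sensor_geometry <- function(rx = 0, ry = -0.05, rz = -0.2) {
  r <- c(x = rx, y = ry, z = rz)
  if (!all(is.finite(r))) {
    stop("sensor geometry must be finite", call. = FALSE)
  }
  if (sqrt(sum(r^2)) <= 0) {
    stop("sensor offset |r| must be > 0", call. = FALSE)
  }
  structure(list(r = r), class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf("<sensor_geometry> r = (%g, %g, %g) m\n",
              x$r[1], x$r[2], x$r[3]))
  invisible(x)
}

#' Gyroscope differentiator settings
#'
#' The angular acceleration is obtained by passing the gyroscope signal
#' through the band-limited differentiator `D(s) = s / (1 + n s)`, a pure
#' derivative rolled off by a first-order lag with time constant `n`. The
#' default `n = 0.01` s leaves gait-band content (< 10 Hz) essentially
#' untouched while bounding high-frequency gain.
#'
#' @param n Time constant of the first-order roll-off, seconds.
#' @param dt Sampling interval, seconds (default 0.01, i.e. 100 Hz).
#' @return An object of class `differentiator_spec`.
#' @export
differentiator_spec <- function(n = 0.01, dt = 0.01) {
  if (!is.finite(n) || n <= 0) stop("time constant n must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("sampling interval dt must be > 0", call. = FALSE)
  structure(list(n = n, dt = dt), class = "differentiator_spec")
}

#' @export
print.differentiator_spec <- function(x, ...) {
  cat(sprintf("<differentiator_spec> n = %g s, dt = %g s\n", x$n, x$dt))
  invisible(x)
}

# Elementary rotations (active, right-handed, column-vector convention).
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Body-to-reference rotation matrix from Euler angles
#'
#' Composes `R0 = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`. `R0` maps vectors from
#' the sensor (body) frame to the reference frame; its transpose brings
#' reference-frame vectors (gravity, the magnetic field) into sensor
#' coordinates.
#'
#' @param roll,pitch,yaw Euler angles in radians.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(roll, pitch, yaw) {
  rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)
}

# Wrap angle(s) to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
}
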