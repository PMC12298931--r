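#' Initial roll and pitch from a static accelerometer sample
#'
#' While the wearer stands still, the accelerometer reads pure gravity, so the
#' tilt follows from the two-argument arctangent of its components:
#' `roll = atan2(Ay, Az)`, `pitch = atan2(-Ax, sqrt(Ay^2 + Az^2))`, both in
#' (-pi, pi).
#'
#' @param accel Accelerometer output at rest, m/s^2 (3-vector).
#' @return Named vector `c(roll, pitch)` in radians.
#' @export
initial_tilt_from_accel <- function(accel) {
  stop_if_not_finite(accel, "accel")
  if (sqrt(sum(accel^2)) <= .Machine$double.eps) {
    stop("degenerate accelerometer sample (zero norm)", call. = FALSE)
  }
  c(roll = atan2(accel[[2]], accel[[3]]),
    pitch = atan2(-accel[[1]], sqrt(accel[[2]]^2 + accel[[3]]^2)))
}

#' Tilt-compensated magnetometer heading
#'
#' Rotates the raw magnetometer output by the current roll and pitch so the
#' heading can be read from the horizontal field components. The correction
#' matrix is `Ry(pitch) Rx(roll)` (a rotation, so the field norm is
#' preserved), and the yaw follows as `atan2(-myc, mxc)` in (-pi, pi).
#'
#' @param mag Raw magnetometer 3-vector, any consistent unit.
#' @param roll,pitch Current attitude, radians.
#' @return List with `mag_c` (corrected field, same units) and `yaw` (rad).
#' @export
tilt_compensate_and_yaw <- function(mag, roll, pitch) {
  stop_if_not_finite(mag, "mag")
  if (sqrt(sum(mag^2)) <= .Machine$double.eps) {
    stop("degenerate magnetometer sample (zero norm)", call. = FALSE)
  }
  sr <- sin(roll); cr <- cos(roll)
  sp <- sin(pitch); cp <- cos(pitch)
  m <- as.numeric(mag)
  mag_c <- c(
    x = cp * m[1] + sr * sp * m[2] + cr * sp * m[3],
    y = cr * m[2] - sr * m[3],
    z = -sp * m[1] + sr * cp * m[2] + cr * cp * m[3]
  )
  if (abs(mag_c[1]) <= .Machine$double.eps &&
      abs(mag_c[2]) <= .Machine$double.eps) {
    stop("heading undefined: corrected horizontal field is zero", call. = FALSE)
  }
  list(mag_c = mag_c, yaw = atan2(-mag_c[[2]], mag_c[[1]]))
}

# Internal state convention: x = (yaw, pitch, roll), matching the filter's
# state-equation ordering. User-facing poses are (roll, pitch, yaw).
PITCH_GUARD <- 89 * pi / 180

guard_pitch <- function(theta) {
  sign(theta) * pmin(abs(theta), PITCH_GUARD)
}

# Forward-Euler step of the Euler-angle kinematics, state order (yaw, pitch,
# roll). Returns the propagated state; attribute "gimbal" marks a clamped
# pitch.
state_transition_psi <- function(x, gyro, dt) {
  psi <- x[1]; theta <- x[2]; phi <- x[3]
  gimbal <- abs(theta) > PITCH_GUARD
  thg <- guard_pitch(theta)
  sec_t <- 1 / cos(thg); tan_t <- tan(thg)
  sf <- sin(phi); cf <- cos(phi)
  wx <- gyro[1]; wy <- gyro[2]; wz <- gyro[3]
  out <- c(psi + dt * sec_t * (sf * wy + cf * wz),
           theta + dt * (cf * wy - sf * wz),
           phi + dt * (wx + tan_t * (sf * wy + cf * wz)))
  attr(out, "gimbal") <- gimbal
  out
}

#' One-step state transition of the Euler-angle kinematics
#'
#' Propagates roll, pitch, yaw one sample forward by a forward-Euler step of
#' the body-rate-to-Euler-rate kinematics
#' (`roll_dot = wx + tan(pitch)(sin(roll) wy + cos(roll) wz)`, etc.). Near
#' gimbal lock the pitch used inside `sec`/`tan` is clamped at 89 degrees and
#' the result carries attribute `gimbal = TRUE`.
#'
#' @param pose Named or plain 3-vector `(roll, pitch, yaw)`, radians.
#' @param gyro Body angular velocity `(wx, wy, wz)`, rad/s.
#' @param dt Time step, seconds.
#' @return Propagated `(roll, pitch, yaw)` in radians.
#' @export
state_transition <- function(pose, gyro, dt) {
  stop_if_not_finite(c(pose, gyro, dt), "state_transition inputs")
  x <- state_transition_psi(c(pose[[3]], pose[[2]], pose[[1]]), gyro, dt)
  out <- c(roll = x[[3]], pitch = x[[2]], yaw = x[[1]])
  attr(out, "gimbal") <- attr(x, "gimbal")
  out
}

# Observation model, state order (yaw, pitch, roll):
# H(x) = (yaw, R0' g_o) with accel rows g (-sin th, sin ph cos th, cos ph cos th).
observation_psi <- function(x, gravity) {
  theta <- x[2]; phi <- x[3]
  c(x[1],
    -gravity * sin(theta),
    gravity * sin(phi) * cos(theta),
    gravity * cos(phi) * cos(theta))
}

#' Predicted observation for a given pose
#'
#' Returns the 4-vector the filter expects to observe at `pose`: the
#' magnetometer-derived yaw and the gravity vector projected into the sensor
#' frame, `(yaw, -g sin(pitch), g sin(roll) cos(pitch), g cos(roll) cos(pitch))`.
#'
#' @param pose `(roll, pitch, yaw)` in radians.
#' @param gravity Gravitational constant, m/s^2.
#' @return Numeric 4-vector `(yaw, ax, ay, az)`.
#' @export
observation_model <- function(pose, gravity = 9.8) {
  stop_if_not_finite(pose, "pose")
  observation_psi(c(pose[[3]], pose[[2]], pose[[1]]), gravity)
}

# Analytic Jacobians wrt state (yaw, pitch, roll).
fjac_psi <- function(x, gyro, dt) {
  theta <- guard_pitch(x[2]); phi <- x[3]
  sf <- sin(phi); cf <- cos(phi)
  ct <- cos(theta)
  sec_t <- 1 / ct; tan_t <- sin(theta) / ct
  wy <- gyro[2]; wz <- gyro[3]
  s_mix <- sf * wy + cf * wz     # appears with sec/tan terms
  c_mix <- cf * wy - sf * wz
  matrix(c(
    1, 0, 0,
    dt * sec_t * tan_t * s_mix, 1, dt * sec_t^2 * s_mix,
    dt * sec_t * c_mix, -dt * s_mix, 1 + dt * tan_t * c_mix
  ), nrow = 3)
}

hjac_psi <- function(x, gravity) {
  theta <- x[2]; phi <- x[3]
  sf <- sin(phi); cf <- cos(phi)
  st <- sin(theta); ct <- cos(theta)
  matrix(c(
    1, 0, 0, 0,
    0, -gravity * ct, -gravity * sf * st, -gravity * cf * st,
    0, 0, gravity * cf * ct, -gravity * sf * ct
  ), nrow = 4)
}

jacobians_psi <- function(x, gyro, dt, gravity) {
  list(f = fjac_psi(x, gyro, dt), h = hjac_psi(x, gravity))
}

#' Analytic Jacobians of the state-transition and observation models
#'
#' Partial derivatives of the forward-Euler state transition (`f`, 3x3) and
#' of the observation model (`h`, 4x3) with respect to the state, evaluated
#' analytically. Rows/columns are ordered (yaw, pitch, roll) to match the
#' filter's internal state vector.
#'
#' @param pose `(roll, pitch, yaw)` in radians.
#' @param gyro Body rates, rad/s.
#' @param dt Time step, seconds.
#' @param gravity Gravitational constant, m/s^2.
#' @return List with elements `f` (3x3) and `h` (4x3).
#' @export
compute_jacobians <- function(pose, gyro, dt, gravity = 9.8) {
  stop_if_not_finite(c(pose, gyro), "compute_jacobians inputs")
  jacobians_psi(c(pose[[3]], pose[[2]], pose[[1]]), gyro, dt, gravity)
}

#' Noise-adaptation coefficients for the filter covariances
#'
#' The process noise grows with gyroscope activity,
#' `Omega_w = a |w|^2 + b`, and the observation noise grows with disturbance
#' of the two reference fields: `Omega_m = c (|m_c|^2 - m_bar) + d` for the
#' heading channel and `Omega_a = e (Ax^2 + Ay^2 + (Az - g)^2) + f` for the
#' accelerometer channels. `b`, `d`, `f` are baseline variances (must be
#' positive); `a`, `c`, `e` scale the adaptation. `m_bar` is the time-average
#' of the squared magnetometer norm over the record (filled in by
#' [run_pose_estimation()] when `NA`).
#'
#' The defaults suit typical MEMS sensors during gait: the gyroscope is
#' trusted strongly (`a`, `b` small), the accelerometer is down-weighted
#' sharply whenever its norm departs from gravity (`e` large, so swing-phase
#' motion acceleration barely perturbs the tilt estimate), and the heading
#' baseline `d` dominates the adaptive term for field-magnitude fluctuations
#' up to about 10%, keeping the heading variance safely positive. They are a
#' starting point; [tune_noise_parameters()] refines them per record.
#'
#' @param a,b Process-noise coefficients (rad^2 per step scale).
#' @param c,d Heading observation-noise coefficients (rad^2 scale).
#' @param e,f Accelerometer observation-noise coefficients ((m/s^2)^2 scale).
#' @param m_bar Mean squared magnetometer norm; `NA` to compute per record.
#' @return Object of class `noise_tuning_params`.
#' @export
noise_tuning_params <- function(a = 1e-7, b = 1e-8, c = 0.1, d = 0.01,
                                e = 100, f = 0.05, m_bar = NA_real_) {
  if (!all(is.finite(c(a, b, c, d, e, f)))) {
    stop("noise tuning parameters must be finite", call. = FALSE)
  }
  if (b <= 0 || d <= 0 || f <= 0) {
    stop("baseline variances b, d, f must be > 0", call. = FALSE)
  }
  if (a < 0 || c < 0 || e < 0) {
    stop("adaptation gains a, c, e must be >= 0", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f, m_bar = m_bar),
            class = "noise_tuning_params")
}

#' @export
print.noise_tuning_params <- function(x, ...) {
  cat(sprintf(
    "<noise_tuning_params> a=%.3g b=%.3g c=%.3g d=%.3g e=%.3g f=%.3g m_bar=%.4g\n",
    x$a, x$b, x$c, x$d, x$e, x$f, x$m_bar))
  invisible(x)
}

COV_FLOOR <- 1e-9

#' Adaptive process-noise covariance
#'
#' @param gyro Body rates, rad/s (3-vector).
#' @param params A [noise_tuning_params()].
#' @return 3x3 diagonal matrix `diag(Omega_w)` with
#'   `Omega_w = a |gyro|^2 + b`, floored at 1e-9.
#' @export
adaptive_process_noise <- function(gyro, params) {
  stopifnot(inherits(params, "noise_tuning_params"))
  omega_w <- max(params$a * sum(gyro^2) + params$b, COV_FLOOR)
  diag(rep(omega_w, 3))
}

#' Adaptive observation-noise covariance
#'
#' @param accel Accelerometer sample, m/s^2 (3-vector).
#' @param mag_sq Squared norm of the tilt-compensated magnetometer sample
#'   (equal to the raw squared norm, since the correction is a rotation).
#' @param params A [noise_tuning_params()] with `m_bar` set.
#' @param gravity Gravitational constant, m/s^2.
#' @return 4x4 diagonal matrix `diag(Omega_m, Omega_a, Omega_a, Omega_a)`,
#'   entries floored at 1e-9; attribute `floored` counts floor hits.
#' @export
adaptive_observation_noise <- function(accel, mag_sq, params, gravity = 9.8) {
  stopifnot(inherits(params, "noise_tuning_params"))
  m_bar <- if (is.finite(params$m_bar)) params$m_bar else mag_sq
  om <- params$c * (mag_sq - m_bar) + params$d
  oa <- params$e * (accel[[1]]^2 + accel[[2]]^2 + (accel[[3]] - gravity)^2) +
    params$f
  floored <- sum(c(om, oa) < COV_FLOOR)
  out <- diag(c(max(om, COV_FLOOR), rep(max(oa, COV_FLOOR), 3)))
  attr(out, "floored") <- floored
  out
}

# Single predict/update cycle on the internal (yaw, pitch, roll) state.
# y = (yaw_mag, ax, ay, az). Returns updated state, covariance and
# diagnostics. Q and R are supplied by the caller (adaptive per sample).
ekf_step_psi <- function(x, P, y, gyro, dt, Q, R) {
  gravity <- attr(R, "gravity") %||% 9.8
  x_pred <- state_transition_psi(x, gyro, dt)
  jac_f <- fjac_psi(x, gyro, dt)          # f at the pre-update state
  P_pred <- jac_f %*% P %*% t(jac_f) + Q
  h <- hjac_psi(x_pred, gravity)          # h at the predicted state
  v <- y - observation_psi(x_pred, gravity)
  v[1] <- wrap_angle(v[1])
  B <- h %*% P_pred %*% t(h) + R
  B <- (B + t(B)) / 2
  ch <- tryCatch(chol(B), error = function(e) {
    stop(sprintf("singular innovation covariance (rcond ~ %.2e)",
                 1 / kappa(B)), call. = FALSE)
  })
  K <- P_pred %*% t(h) %*% chol2inv(ch)
  x_new <- as.numeric(x_pred + K %*% v)
  P_new <- (diag(3) - K %*% h) %*% P_pred
  P_new <- (P_new + t(P_new)) / 2
  list(state = x_new, P = P_new, V = as.numeric(v), B = B, K = K,
       predicted = as.numeric(x_pred),
       gimbal = isTRUE(attr(x_pred, "gimbal")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One extended-Kalman-filter step
#'
#' Performs a single predict/update cycle: forward-Euler propagation of the
#' Euler-angle state with the gyroscope, followed by a measurement update
#' against the 4-dimensional observation (magnetometer yaw and the three
#' accelerometer axes) with the adaptive noise covariances. The updated
#' covariance is re-symmetrised.
#'
#' @param pose Current `(roll, pitch, yaw)`, radians.
#' @param P Current 3x3 state covariance (internal order yaw, pitch, roll).
#' @param y Observation `(yaw_mag, ax, ay, az)`.
#' @param gyro Body rates, rad/s.
#' @param dt Time step, seconds.
#' @param params A [noise_tuning_params()] with `m_bar` set.
#' @param gravity Gravitational constant, m/s^2.
#' @param mag_sq Squared magnetometer norm for this sample; defaults to
#'   `params$m_bar` (undisturbed field).
#' @return List with `pose` (roll, pitch, yaw), `P`, and diagnostics `V`
#'   (innovation), `B` (innovation covariance), `K` (gain), `predicted`
#'   (pre-update pose).
#' @export
ekf_step <- function(pose, P, y, gyro, dt, params, gravity = 9.8,
                     mag_sq = NULL) {
  stopifnot(inherits(params, "noise_tuning_params"))
  if (max(abs(P - t(P))) > 1e-9) stop("P must be symmetric", call. = FALSE)
  Q <- adaptive_process_noise(gyro, params)
  R <- adaptive_observation_noise(y[2:4], mag_sq %||% params$m_bar %||% NA,
                                  params, gravity)
  attr(R, "gravity") <- gravity
  st <- ekf_step_psi(c(pose[[3]], pose[[2]], pose[[1]]), P, as.numeric(y),
                     gyro, dt, Q, R)
  st$pose <- c(roll = st$state[3], pitch = st$state[2], yaw = st$state[1])
  st$predicted <- c(roll = st$predicted[3], pitch = st$predicted[2],
                    yaw = st$predicted[1])
  st$state <- NULL
  st
}

#' Estimate the sensor pose over a full record
#'
#' Runs the complete sensor-fusion pipeline on a 9-axis record: the roll and
#' pitch are initialised from the accelerometer averaged over an initial
#' standing window ([initial_tilt_from_accel()]), the yaw from the
#' tilt-compensated magnetometer ([tilt_compensate_and_yaw()]); every sample
#' is then filtered with the adaptive extended Kalman filter. The initial
#' state covariance is `diag((10 deg)^2, (5 deg)^2, (5 deg)^2)` in (yaw,
#' pitch, roll), reflecting the accuracy of the static initialisation.
#'
#' @param imu An [imu_series()] beginning with a near-static standing phase.
#' @param params A [noise_tuning_params()]; if `m_bar` is `NA` it is set to
#'   the record's mean squared magnetometer norm.
#' @param calibration_window Length of the standing window, seconds
#'   (default 5, the standing phase of the measurement protocol).
#' @param gravity Gravitational constant, m/s^2.
#' @return A `pose_series`: list with `t`, `rpy` (n x 3 matrix of roll,
#'   pitch, yaw in radians), `dt`, `initial` pose, and `diagnostics`
#'   (innovations `V` (n x 4), innovation covariances `B` (4 x 4 x n), gains
#'   `K` (3 x 4 x n), covariances `P` (3 x 3 x n), gimbal/floor counters).
#' @export
run_pose_estimation <- function(imu, params = noise_tuning_params(),
                                calibration_window = 5, gravity = 9.8) {
  stopifnot(inherits(imu, "imu_series"), inherits(params, "noise_tuning_params"))
  n_cal <- round(calibration_window / imu$dt)
  if (n_cal < 1) n_cal <- 1
  if (n_cal > imu$n) {
    stop(sprintf(
      "calibration window (%.2f s) exceeds the record length (%.2f s)",
      calibration_window, imu$n * imu$dt), call. = FALSE)
  }
  cal <- seq_len(n_cal)
  gyro_rms <- sqrt(mean(imu$gyro[cal, ]^2))
  if (gyro_rms > 0.1) {
    warning(sprintf(
      "calibration window is not static (gyro RMS %.3f rad/s > 0.1)", gyro_rms))
  }
  tilt <- initial_tilt_from_accel(colMeans(imu$accel[cal, , drop = FALSE]))
  yaw0 <- tilt_compensate_and_yaw(colMeans(imu$mag[cal, , drop = FALSE]),
                                  tilt[["roll"]], tilt[["pitch"]])$yaw
  if (!is.finite(params$m_bar)) {
    params$m_bar <- mean(rowSums(imu$mag^2))
  }

  x <- c(yaw0, tilt[["pitch"]], tilt[["roll"]])
  P <- diag(c(deg2rad(10)^2, deg2rad(5)^2, deg2rad(5)^2))
  n <- imu$n
  rpy <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("roll", "pitch", "yaw")))
  V <- matrix(NA_real_, n, 4)
  B <- array(NA_real_, c(4, 4, n))
  K <- array(NA_real_, c(3, 4, n))
  Parr <- array(NA_real_, c(3, 3, n))
  gimbal_hits <- 0L
  floor_hits <- 0L
  for (i in seq_len(n)) {
    gyro_i <- imu$gyro[i, ]
    acc_i <- imu$accel[i, ]
    mag_i <- imu$mag[i, ]
    # heading observation from the magnetometer, tilt-compensated with the
    # one-step-ahead prediction of roll/pitch
    x_pred <- state_transition_psi(x, gyro_i, imu$dt)
    tc <- tilt_compensate_and_yaw(mag_i, x_pred[3], x_pred[2])
    y <- c(tc$yaw, acc_i)
    Q <- adaptive_process_noise(gyro_i, params)
    R <- adaptive_observation_noise(acc_i, sum(tc$mag_c^2), params, gravity)
    floor_hits <- floor_hits + (attr(R, "floored") %||% 0L)
    attr(R, "gravity") <- gravity
    st <- ekf_step_psi(x, P, y, gyro_i, imu$dt, Q, R)
    if (st$gimbal) gimbal_hits <- gimbal_hits + 1L
    x <- st$state
    P <- st$P
    rpy[i, ] <- c(x[3], x[2], x[1])
    V[i, ] <- st$V
    B[, , i] <- st$B
    K[, , i] <- st$K
    Parr[, , i] <- P
  }
  if (gimbal_hits > 0) {
    warning(sprintf("pitch clamped near gimbal lock at %d samples", gimbal_hits))
  }
  structure(
    list(t = imu$t, rpy = rpy, dt = imu$dt,
         initial = c(roll = tilt[["roll"]], pitch = tilt[["pitch"]], yaw = yaw0),
         params = params,
         diagnostics = list(V = V, B = B, K = K, P = Parr,
                            gimbal_hits = gimbal_hits,
                            floor_hits = floor_hits)),
    class = "pose_series"
  )
}

#' @export
print.pose_series <- function(x, ...) {
  rng <- apply(rad2deg(x$rpy), 2, range)
  cat(sprintf("<pose_series> %d samples @ %g Hz\n", nrow(x$rpy), 1 / x$dt))
  cat(sprintf("  roll  [%7.2f, %7.2f] deg\n", rng[1, 1], rng[2, 1]))
  cat(sprintf("  pitch [%7.2f, %7.2f] deg\n", rng[1, 2], rng[2, 2]))
  cat(sprintf("  yaw   [%7.2f, %7.2f] deg\n", rng[1, 3], rng[2, 3]))
  invisible(x)
}
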