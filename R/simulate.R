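#' Parameters of the synthetic gait model
#'
#' Configures a closed-form, infinitely differentiable model of shank motion
#' during treadmill-style level walking: sagittal-dominant hip and knee
#' rotation described by truncated Fourier series over the gait cycle, small
#' out-of-plane pitch/yaw oscillation of the shank, and pelvis translation
#' (forward progression plus vertical and lateral oscillation). The record
#' begins with a standing calibration phase; walking amplitude then ramps in
#' smoothly over one cycle (a C2 smoothstep envelope) before `n_cycles`
#' steady cycles.
#'
#' Defaults emulate the measurement protocol the model is meant to stand in
#' for: cadence 90 steps/min (cycle duration 4/3 s), walking speed 1.1 m/s,
#' a 5 s standing lead-in, and noise-free sensors. Angle coefficients are in
#' degrees, displacements in metres.
#'
#' @param cadence Steps per minute (two steps per gait cycle).
#' @param n_cycles Number of steady gait cycles after the ramp-in cycle.
#' @param dt Sampling interval, seconds.
#' @param calibration_time Standing lead-in, seconds.
#' @param tail_time Extra walking time after the last counted cycle, seconds.
#' @param speed Forward walking speed, m/s.
#' @param toe_off_frac Stance fraction of the cycle (toe-off at this phase).
#' @param thigh_length Hip-to-knee segment length, metres.
#' @param hip_coef,knee_coef,pitch_coef,yaw_coef Fourier coefficients (lists
#'   with `a0`, `cos`, `sin`; degrees) of the thigh sagittal angle, knee
#'   flexion, and shank out-of-plane pitch and yaw.
#' @param pelvis_vert_amp,pelvis_lat_amp,pelvis_fwd_amp Oscillation
#'   amplitudes of the pelvis path, metres (vertical and fore-aft at twice
#'   per cycle, lateral at once per cycle).
#' @param geometry A [sensor_geometry()].
#' @param gravity Gravitational constant, m/s^2.
#' @param mag_field Reference magnetic field direction (unit horizontal by
#'   default; set `mag_dip_deg` for an inclined field).
#' @param mag_dip_deg Magnetic dip angle in degrees (positive down); applied
#'   to `mag_field` when non-zero.
#' @param gyro_sd,accel_sd Additive white noise SDs (rad/s, m/s^2).
#' @param mag_sd_frac Magnetometer noise SD as a fraction of the field norm.
#' @param gyro_bias Constant gyroscope bias 3-vector, rad/s.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `gait_model_params`.
#' @export
gait_model_params <- function(cadence = 90, n_cycles = 10, dt = 0.01,
                              calibration_time = 5, tail_time = 0.3,
                              speed = 1.1, toe_off_frac = 0.6,
                              thigh_length = 0.41,
                              hip_coef = list(a0 = 10, cos = c(19.68, 0),
                                              sin = c(-3.59, 0)),
                              knee_coef = default_knee_coef(),
                              pitch_coef = list(a0 = 0, cos = c(0, 0),
                                                sin = c(2, 0.5)),
                              yaw_coef = list(a0 = 0, cos = c(1, 0),
                                              sin = c(3, 0)),
                              pelvis_vert_amp = 0.02, pelvis_lat_amp = 0.03,
                              pelvis_fwd_amp = 0.015,
                              geometry = sensor_geometry(), gravity = 9.8,
                              mag_field = c(1, 0, 0), mag_dip_deg = 0,
                              gyro_sd = 0, accel_sd = 0, mag_sd_frac = 0,
                              gyro_bias = c(0, 0, 0), seed = 1L) {
  if (!is.finite(cadence) || cadence <= 0) stop("cadence must be > 0", call. = FALSE)
  if (n_cycles < 1) stop("need at least one gait cycle", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (thigh_length <= 0) stop("thigh_length must be > 0", call. = FALSE)
  if (toe_off_frac <= 0 || toe_off_frac >= 1) {
    stop("toe_off_frac must lie in (0, 1)", call. = FALSE)
  }
  if (mag_dip_deg != 0) {
    dip <- deg2rad(mag_dip_deg)
    mag_field <- c(cos(dip) * mag_field[1:2] / sqrt(sum(mag_field[1:2]^2)),
                   sin(dip))
  }
  structure(
    list(cadence = cadence, n_cycles = n_cycles, dt = dt,
         calibration_time = calibration_time, tail_time = tail_time,
         speed = speed, toe_off_frac = toe_off_frac,
         thigh_length = thigh_length,
         hip_coef = hip_coef, knee_coef = knee_coef,
         pitch_coef = pitch_coef, yaw_coef = yaw_coef,
         pelvis_vert_amp = pelvis_vert_amp, pelvis_lat_amp = pelvis_lat_amp,
         pelvis_fwd_amp = pelvis_fwd_amp,
         geometry = geometry, gravity = gravity, mag_field = mag_field,
         gyro_sd = gyro_sd, accel_sd = accel_sd, mag_sd_frac = mag_sd_frac,
         gyro_bias = gyro_bias, seed = as.integer(seed),
         cycle_time = 60 / (cadence / 2)),
    class = "gait_model_params"
  )
}

#' Default knee-flexion Fourier coefficients
#'
#' Three-harmonic curve (degrees) shaped after the canonical knee-flexion
#' pattern of level walking: moderate flexion at contact, near-full extension
#' in late stance, and a swing-phase flexion peak of roughly 60 degrees at
#' about 70% of the cycle. Together with the default hip curve it places the
#' shank angular-velocity landmarks (mid-swing positive peak, flanking
#' troughs) at their physiological positions relative to foot contact and
#' toe-off, which is what event detection on the gyroscope relies on.
#'
#' @return Coefficient list with elements `a0`, `cos`, `sin`.
#' @export
default_knee_coef <- function() {
  list(a0 = 21.75,
       cos = c(-3.52, -10.75, 6.46),
       sin = c(-17.19, 10.04, 6.68))
}

#' @export
print.gait_model_params <- function(x, ...) {
  cat(sprintf(
    "<gait_model_params> cadence %g steps/min (cycle %.3f s), %d cycles, dt %g s\n",
    x$cadence, x$cycle_time, x$n_cycles, x$dt))
  cat(sprintf("  speed %.2f m/s, calibration %.1f s, noise (gyro %.3g, accel %.3g, mag %.3g)\n",
              x$speed, x$calibration_time, x$gyro_sd, x$accel_sd, x$mag_sd_frac))
  invisible(x)
}

# Evaluate a truncated Fourier series (and time-derivatives) over phase
# u = 2*pi*tt/Tcyc. coef: list(a0, cos, sin). deriv in 0:2.
fourier_eval <- function(tt, Tcyc, coef, deriv = 0) {
  u <- 2 * pi * tt / Tcyc
  out <- if (deriv == 0) rep(coef$a0 %||% 0, length(tt)) else numeric(length(tt))
  K <- max(length(coef$cos), length(coef$sin))
  for (k in seq_len(K)) {
    ak <- if (k <= length(coef$cos)) coef$cos[k] else 0
    bk <- if (k <= length(coef$sin)) coef$sin[k] else 0
    wk <- 2 * pi * k / Tcyc
    out <- out + switch(deriv + 1,
      ak * cos(k * u) + bk * sin(k * u),
      wk * (-ak * sin(k * u) + bk * cos(k * u)),
      wk^2 * (-ak * cos(k * u) - bk * sin(k * u)))
  }
  out
}

# C2 smoothstep ramp from 0 at t0 to 1 at t0+Tr, with derivatives.
smoothstep <- function(t, t0, Tr, deriv = 0) {
  s <- pmin(pmax((t - t0) / Tr, 0), 1)
  inside <- (t > t0) & (t < t0 + Tr)
  switch(deriv + 1,
    6 * s^5 - 15 * s^4 + 10 * s^3,
    ifelse(inside, (30 * s^4 - 60 * s^3 + 30 * s^2) / Tr, 0),
    ifelse(inside, (120 * s^3 - 180 * s^2 + 60 * s) / Tr^2, 0))
}

# value/derivatives of envelope * series (product rule)
enveloped <- function(t, t0, Tr, Tcyc, coef) {
  tt <- t - t0
  w0 <- smoothstep(t, t0, Tr, 0)
  w1 <- smoothstep(t, t0, Tr, 1)
  w2 <- smoothstep(t, t0, Tr, 2)
  f0 <- fourier_eval(tt, Tcyc, coef, 0)
  f1 <- fourier_eval(tt, Tcyc, coef, 1)
  f2 <- fourier_eval(tt, Tcyc, coef, 2)
  list(v = w0 * f0,
       d1 = w1 * f0 + w0 * f1,
       d2 = w2 * f0 + 2 * w1 * f1 + w0 * f2)
}

#' Generate ground-truth shank kinematics for synthetic gait
#'
#' Evaluates the closed-form gait model on the sampling grid and returns the
#' exact pose, body angular velocity/acceleration, knee-centre acceleration
#' and gait events. Body rates follow analytically from the Euler angles and
#' their derivatives (`wx = roll' - yaw' sin(pitch)`, ...), and the
#' knee-centre path is pelvis translation plus the thigh-segment swing, so
#' every derivative is exact (no numerical differentiation anywhere).
#'
#' @param params A [gait_model_params()].
#' @return Object of class `gait_truth`: `t`, `rpy` (roll/pitch/yaw, rad),
#'   `omega`, `omega_dot` (sensor-frame rates, rad/s, rad/s^2),
#'   `knee_acc_world` and `knee_acc_sensor` (m/s^2; the latter is the true
#'   translational component), `events` (a [gait_events()]), and `params`.
#' @export
generate_leg_trajectory <- function(params) {
  stopifnot(inherits(params, "gait_model_params"))
  Tcyc <- params$cycle_time
  t_walk <- params$calibration_time
  t_end <- t_walk + (1 + params$n_cycles) * Tcyc + params$tail_time
  t <- seq(0, t_end, by = params$dt)

  hip <- enveloped(t, t_walk, Tcyc, Tcyc, lapply_deg(params$hip_coef))
  knee <- enveloped(t, t_walk, Tcyc, Tcyc, lapply_deg(params$knee_coef))
  pit <- enveloped(t, t_walk, Tcyc, Tcyc, lapply_deg(params$pitch_coef))
  yaw <- enveloped(t, t_walk, Tcyc, Tcyc, lapply_deg(params$yaw_coef))

  roll <- list(v = hip$v - knee$v, d1 = hip$d1 - knee$d1, d2 = hip$d2 - knee$d2)

  # body rates from Euler angles and rates (exact inverse of the Euler-rate
  # kinematics for R0 = Rz(yaw) Ry(pitch) Rx(roll))
  sph <- sin(roll$v); cph <- cos(roll$v)
  sth <- sin(pit$v); cth <- cos(pit$v)
  wx <- roll$d1 - yaw$d1 * sth
  wy <- pit$d1 * cph + yaw$d1 * cth * sph
  wz <- -pit$d1 * sph + yaw$d1 * cth * cph
  wx_d <- roll$d2 - yaw$d2 * sth - yaw$d1 * pit$d1 * cth
  wy_d <- pit$d2 * cph - pit$d1 * roll$d1 * sph + yaw$d2 * cth * sph +
    yaw$d1 * (-pit$d1 * sth * sph + roll$d1 * cth * cph)
  wz_d <- -pit$d2 * sph - pit$d1 * roll$d1 * cph + yaw$d2 * cth * cph +
    yaw$d1 * (-pit$d1 * sth * cph - roll$d1 * cth * sph)

  # pelvis (hip-point) path: world frame x lateral, y forward, z down
  lat <- enveloped(t, t_walk, Tcyc, Tcyc,
                   list(a0 = 0, cos = numeric(0), sin = params$pelvis_lat_amp))
  vert <- enveloped(t, t_walk, Tcyc, Tcyc,
                    list(a0 = 0, cos = c(0, params$pelvis_vert_amp),
                         sin = c(0, 0)))
  fosc <- enveloped(t, t_walk, Tcyc, Tcyc,
                    list(a0 = 0, cos = c(0, 0), sin = c(0, params$pelvis_fwd_amp)))
  w0 <- smoothstep(t, t_walk, Tcyc, 0)
  w1 <- smoothstep(t, t_walk, Tcyc, 1)
  w2 <- smoothstep(t, t_walk, Tcyc, 2)
  tt <- t - t_walk
  fwd_d2 <- fosc$d2 + params$speed * (w2 * tt + 2 * w1)

  # knee point = pelvis + thigh segment; thigh sagittal angle = hip flexion
  La <- params$thigh_length
  a <- hip  # thigh sagittal angle (rad) and derivatives
  d2_sin <- a$d2 * cos(a$v) - a$d1^2 * sin(a$v)
  d2_cos <- -a$d2 * sin(a$v) - a$d1^2 * cos(a$v)
  knee_acc_world <- cbind(x = lat$d2,
                          y = fwd_d2 + La * d2_sin,
                          z = vert$d2 + La * d2_cos)

  rpy <- cbind(roll = roll$v, pitch = pit$v, yaw = yaw$v)
  omega <- cbind(x = wx, y = wy, z = wz)
  omega_dot <- cbind(x = wx_d, y = wy_d, z = wz_d)
  knee_acc_sensor <- world_to_sensor(knee_acc_world, rpy)

  contacts <- t_walk + Tcyc * (1 + 0:params$n_cycles)
  toe_offs <- t_walk + Tcyc * (1 + 0:(params$n_cycles - 1) + params$toe_off_frac)
  structure(
    list(t = t, rpy = rpy, omega = omega, omega_dot = omega_dot,
         knee_acc_world = knee_acc_world, knee_acc_sensor = knee_acc_sensor,
         events = gait_events(contacts, toe_offs),
         params = params),
    class = "gait_truth"
  )
}

lapply_deg <- function(coef) {
  list(a0 = deg2rad(coef$a0 %||% 0), cos = deg2rad(coef$cos),
       sin = deg2rad(coef$sin))
}

# rotate world-frame row vectors into the sensor frame, sample by sample
world_to_sensor <- function(vw, rpy) {
  out <- matrix(NA_real_, nrow(vw), 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(nrow(vw))) {
    R0 <- euler_to_rotation(rpy[i, 1], rpy[i, 2], rpy[i, 3])
    out[i, ] <- crossprod(R0, vw[i, ])
  }
  out
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %d samples, %d gait cycles @ cadence %g\n",
              length(x$t), x$params$n_cycles, x$params$cadence))
  cat(sprintf("  roll range [%.1f, %.1f] deg, |omega| peak %.2f rad/s\n",
              min(rad2deg(x$rpy[, 1])), max(rad2deg(x$rpy[, 1])),
              max(sqrt(rowSums(x$omega^2)))))
  invisible(x)
}

#' True acceleration components of a synthetic record
#'
#' Emits the exact per-sample gravitational, centrifugal, tangential and
#' translational vectors used in synthesis, for scoring recovery. By
#' construction the components sum to the noiseless accelerometer signal.
#'
#' @param truth A `gait_truth` from [generate_leg_trajectory()].
#' @return An `accel_components` object (with an empty transient set).
#' @export
ground_truth_components <- function(truth) {
  stopifnot(inherits(truth, "gait_truth"))
  p <- truth$params
  grav <- gravity_in_sensor_frame(truth$rpy, p$gravity)
  cen <- centrifugal_acceleration(truth$omega, p$geometry)
  tng <- tangential_acceleration(truth$omega_dot, p$geometry)
  tra <- truth$knee_acc_sensor
  colnames(tra) <- c("x", "y", "z")
  col <- matrix(0, length(truth$t), 3, dimnames = list(NULL, c("x", "y", "z")))
  structure(
    list(t = truth$t, grav = grav, cen = cen, tan = tng, tra = tra, col = col,
         raw = grav + cen + tng + tra, transient = integer(0),
         gravity = p$gravity),
    class = "accel_components"
  )
}

#' Synthesize a 9-axis IMU record from ground-truth kinematics
#'
#' Builds the ideal sensor outputs implied by the rigid-body model --
#' gyroscope = body rates, accelerometer = knee-centre acceleration plus
#' centrifugal, tangential and gravity terms, magnetometer = reference field
#' in sensor coordinates -- then adds Gaussian noise and a constant gyro bias
#' per the parameters. All randomness is fixed by `params$seed`.
#'
#' @param truth A `gait_truth` from [generate_leg_trajectory()].
#' @param params A [gait_model_params()]; defaults to `truth$params`.
#' @return An [imu_series()].
#' @export
synthesize_imu <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "gait_truth"))
  comp <- ground_truth_components(truth)
  n <- length(truth$t)
  gyro <- truth$omega
  accel <- comp$raw
  mag <- world_to_sensor(matrix(params$mag_field, n, 3, byrow = TRUE),
                         truth$rpy)
  if (params$gyro_sd > 0 || params$accel_sd > 0 || params$mag_sd_frac > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(params$seed)
    gyro <- gyro + matrix(stats::rnorm(3 * n, sd = params$gyro_sd), n, 3)
    accel <- accel + matrix(stats::rnorm(3 * n, sd = params$accel_sd), n, 3)
    mag <- mag + matrix(stats::rnorm(3 * n,
                                     sd = params$mag_sd_frac *
                                       sqrt(sum(params$mag_field^2))), n, 3)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  gyro <- sweep(gyro, 2, params$gyro_bias, "+")
  imu_series(gyro, accel, mag, params$dt, t0 = 0)
}

#' Simulate a complete synthetic gait record
#'
#' Convenience wrapper: [generate_leg_trajectory()] then [synthesize_imu()].
#'
#' @param params A [gait_model_params()].
#' @return List with `imu` (an [imu_series()]), `truth` (a `gait_truth`) and
#'   `components` (the true [ground_truth_components()]).
#' @export
simulate_gait_imu <- function(params = gait_model_params()) {
  truth <- generate_leg_trajectory(params)
  list(imu = synthesize_imu(truth, params), truth = truth,
       components = ground_truth_components(truth))
}
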