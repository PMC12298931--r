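# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# memoised default-condition simulations (seed 1)
fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

sim_clean <- function() {
  fixture("clean", function() simulate_gait_imu(gait_model_params(seed = 1)))
}

sim_noisy <- function() {
  fixture("noisy", function() {
    simulate_gait_imu(gait_model_params(seed = 1, gyro_sd = 0.01,
                                        accel_sd = 0.1, mag_sd_frac = 0.01))
  })
}

pose_clean <- function() {
  fixture("pose_clean", function() {
    run_pose_estimation(sim_clean()$imu, calibration_window = 5)
  })
}

# ideal static record at a fixed pose
static_imu <- function(n, rpy = c(0, 0, 0), dt = 0.01, g = 9.8,
                       mag_world = c(1, 0, 0)) {
  R0 <- euler_to_rotation(rpy[1], rpy[2], rpy[3])
  acc <- as.numeric(crossprod(R0, c(0, 0, g)))
  mag <- as.numeric(crossprod(R0, mag_world))
  imu_series(matrix(0, n, 3), matrix(acc, n, 3, byrow = TRUE),
             matrix(mag, n, 3, byrow = TRUE), dt)
}

# static lead-in followed by a constant roll rate, with consistent accel/mag
const_roll_imu <- function(rate_deg_s, t_static = 1, t_roll = 2, dt = 0.01,
                           g = 9.8) {
  t <- seq(0, t_static + t_roll, by = dt)
  roll <- pmax(0, t - t_static) * deg(rate_deg_s)
  gyro <- cbind(ifelse(t > t_static, deg(rate_deg_s), 0), 0, 0)
  acc <- t(vapply(roll, function(r)
    as.numeric(crossprod(euler_to_rotation(r, 0, 0), c(0, 0, g))), numeric(3)))
  mag <- t(vapply(roll, function(r)
    as.numeric(crossprod(euler_to_rotation(r, 0, 0), c(1, 0, 0))), numeric(3)))
  imu_series(gyro, acc, mag, dt)
}

deg <- function(x) x * pi / 180

pose_rmse_deg <- function(poses, truth) {
  e <- poses$rpy - truth$rpy
  e[, 3] <- ((e[, 3] + pi) %% (2 * pi)) - pi
  sqrt(colMeans(e^2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
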