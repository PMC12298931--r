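test_that("zero-amplitude parameters give a static standing record", {
  zero <- list(a0 = 0, cos = c(0, 0), sin = c(0, 0))
  params <- gait_model_params(hip_coef = zero, knee_coef = zero,
                              pitch_coef = zero, yaw_coef = zero,
                              pelvis_vert_amp = 0, pelvis_lat_amp = 0,
                              pelvis_fwd_amp = 0, speed = 0, n_cycles = 1,
                              calibration_time = 1)
  sim <- simulate_gait_imu(params)
  expect_lt(max(abs(sim$truth$rpy)), 1e-15)
  expect_lt(max(abs(sim$truth$omega)), 1e-15)
  expect_lt(max(abs(sim$imu$gyro)), 1e-15)
  expect_true(all(abs(sweep(sim$imu$accel, 2, c(0, 0, 9.8))) < 1e-12))
  expect_lt(max(abs(sim$components$tra)), 1e-12)
})

test_that("cadence sets the cycle duration (two steps per cycle)", {
  params <- gait_model_params(cadence = 90)
  expect_equal(params$cycle_time, 60 / 45)
  ev <- generate_leg_trajectory(params)$events
  expect_equal(unique(round(diff(ev$foot_contacts), 10)), round(60 / 45, 10))
  expect_error(gait_model_params(cadence = 0), "cadence")
  expect_error(gait_model_params(thigh_length = -1), "thigh_length")
})

test_that("stored pose differentiates to the stored body rates", {
  # refined sampling + 5-point stencil so the numerical check is far more
  # accurate than the 1e-6 contract being verified
  params <- gait_model_params(dt = 1e-3, n_cycles = 1, calibration_time = 0.5,
                              tail_time = 0.1)
  tr <- generate_leg_trajectory(params)
  h <- params$dt
  n <- length(tr$t)
  mid <- seq(3, n - 2)
  # the ramp-in envelope is C2, so its junctions (walking onset and one cycle
  # later) are excluded: finite differences of the angular rates lose accuracy
  # exactly where the third derivative jumps
  junctions <- c(params$calibration_time,
                 params$calibration_time + params$cycle_time)
  near_junction <- vapply(tr$t[mid], function(x)
    any(abs(x - junctions) < 3 * h), logical(1))
  mid <- mid[!near_junction]
  d5 <- function(m) {
    (m[mid - 2, ] - 8 * m[mid - 1, ] + 8 * m[mid + 1, ] - m[mid + 2, ]) / (12 * h)
  }
  rate <- d5(tr$rpy)
  sph <- sin(tr$rpy[mid, 1]); cph <- cos(tr$rpy[mid, 1])
  sth <- sin(tr$rpy[mid, 2]); cth <- cos(tr$rpy[mid, 2])
  w_num <- cbind(rate[, 1] - rate[, 3] * sth,
                 rate[, 2] * cph + rate[, 3] * cth * sph,
                 -rate[, 2] * sph + rate[, 3] * cth * cph)
  expect_lt(max(abs(w_num - tr$omega[mid, ])), 1e-6)
  # angular acceleration consistent with the rates
  wd_num <- d5(tr$omega)
  expect_lt(max(abs(wd_num - tr$omega_dot[mid, ])), 1e-6)
})

test_that("ground-truth components sum to the noiseless accelerometer signal", {
  sim <- sim_clean()
  comp <- sim$components
  resid <- comp$grav + comp$cen + comp$tan + comp$tra - comp$raw
  expect_lt(max(abs(resid)), 1e-12)
  expect_equal(comp$raw, sim$imu$accel, tolerance = 1e-15)
  # gravity component norm is exactly g
  expect_lt(max(abs(sqrt(rowSums(comp$grav^2)) - 9.8)), 1e-12)
})

test_that("constant rotation about the sensor x axis gives pure centripetal accel", {
  # directly exercise the generative model: fixed knee centre, constant rate
  dt <- 0.01
  t <- seq(0, 3, by = dt)
  rate <- 2
  rpy <- cbind(rate * t, 0, 0)
  geom <- sensor_geometry(0, -0.05, -0.2)
  truth <- structure(
    list(t = t, rpy = rpy,
         omega = cbind(rep(rate, length(t)), 0, 0),
         omega_dot = matrix(0, length(t), 3),
         knee_acc_world = matrix(0, length(t), 3),
         knee_acc_sensor = matrix(0, length(t), 3),
         events = gait_events(c(0, 1), 0.5),
         params = gait_model_params(geometry = geom)),
    class = "gait_truth")
  imu <- synthesize_imu(truth)
  grav <- gravity_in_sensor_frame(rpy)
  cen_expect <- centrifugal_acceleration(truth$omega, geom)
  expect_lt(max(abs(imu$accel - grav - cen_expect)), 1e-12)
})

test_that("simulation is deterministic given the seed and responds to noise", {
  p <- gait_model_params(seed = 7, n_cycles = 1, calibration_time = 1,
                         gyro_sd = 0.01, accel_sd = 0.1, mag_sd_frac = 0.01)
  a <- simulate_gait_imu(p)
  b <- simulate_gait_imu(p)
  expect_identical(a$imu$gyro, b$imu$gyro)
  expect_identical(a$imu$accel, b$imu$accel)
  expect_identical(a$imu$mag, b$imu$mag)
  p2 <- gait_model_params(seed = 8, n_cycles = 1, calibration_time = 1,
                          gyro_sd = 0.01, accel_sd = 0.1, mag_sd_frac = 0.01)
  expect_false(identical(simulate_gait_imu(p2)$imu$gyro, a$imu$gyro))
  # noiseless synthesis is exactly the component sum (no RNG consumed)
  p0 <- gait_model_params(seed = 7, n_cycles = 1, calibration_time = 1)
  s0 <- simulate_gait_imu(p0)
  expect_identical(s0$imu$accel, s0$components$raw)
})

test_that("doubling the angle amplitudes doubles the peak sagittal rate", {
  scale_coef <- function(cf, s) list(a0 = cf$a0 * s, cos = cf$cos * s,
                                     sin = cf$sin * s)
  zero <- list(a0 = 0, cos = 0, sin = 0)
  base <- gait_model_params(pitch_coef = zero, yaw_coef = zero)
  doubled <- gait_model_params(
    hip_coef = scale_coef(base$hip_coef, 2),
    knee_coef = scale_coef(base$knee_coef, 2),
    pitch_coef = zero, yaw_coef = zero)
  w1 <- generate_leg_trajectory(base)$omega
  w2 <- generate_leg_trajectory(doubled)$omega
  expect_equal(max(abs(w2[, 1])), 2 * max(abs(w1[, 1])), tolerance = 1e-12)
})

test_that("a magnetic dip angle tilts the reference field as configured", {
  p <- gait_model_params(mag_dip_deg = 50)
  expect_equal(p$mag_field, c(cos(deg(50)), 0, sin(deg(50))))
  expect_equal(sqrt(sum(p$mag_field^2)), 1)
})
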