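test_that("centrifugal and tangential formulas match nested cross products", {
  geom <- sensor_geometry(0, -0.05, -0.2)
  # frozen examples (double cross product / cross product by hand)
  expect_equal(centrifugal_acceleration(c(0, 0, 0), geom), c(x = 0, y = 0, z = 0))
  expect_equal(centrifugal_acceleration(c(2, 0, 0), geom),
               c(x = 0, y = 0.2, z = 0.8))
  expect_equal(tangential_acceleration(c(0, 0, 0), geom), c(x = 0, y = 0, z = 0))
  expect_equal(tangential_acceleration(c(10, 0, 0), geom),
               c(x = 0, y = 2.0, z = -0.5))
  # oracle equivalence over random inputs
  set.seed(42)
  for (i in 1:1000) {
    w <- stats::rnorm(3, sd = 3)
    wd <- stats::rnorm(3, sd = 30)
    r <- stats::rnorm(3, sd = 0.2)
    g <- sensor_geometry(r[1], r[2], r[3])
    expect_lt(max(abs(centrifugal_acceleration(w, g) - cross3(w, cross3(w, r)))),
              1e-12)
    expect_lt(max(abs(tangential_acceleration(wd, g) - cross3(wd, r))), 1e-12)
  }
  # matrix input agrees with rowwise evaluation
  W <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(centrifugal_acceleration(W, geom)[4, ],
               centrifugal_acceleration(W[4, ], geom))
  expect_error(centrifugal_acceleration(c(1, NA, 0), geom), "non-finite")
  expect_error(tangential_acceleration(c(Inf, 0, 0), geom), "non-finite")
})

test_that("differentiator has the analytic frequency response and settles", {
  spec <- differentiator_spec(n = 0.01, dt = 0.01)
  t <- seq(0, 10, by = 0.01)
  # constant input -> zero after the transient
  y_const <- differentiate_gyro(rep(2.5, length(t)), spec)
  expect_lt(max(abs(y_const[-(1:attr(y_const, "transient"))])), 1e-9)
  # ramp with slope k -> steady state k within 0.1% after 10 n seconds
  k <- 1.7
  y_ramp <- differentiate_gyro(k * t, spec)
  late <- t > 10 * spec$n
  expect_lt(max(abs(y_ramp[late] - k)) / k, 0.001)
  # sinusoid at 1 Hz: steady-state gain |D(j 2 pi f)| within 1%
  y_sin <- differentiate_gyro(sin(2 * pi * t), spec)
  steady <- t > 1
  gain <- (max(y_sin[steady]) - min(y_sin[steady])) / 2
  gain_true <- 2 * pi / sqrt(1 + (2 * pi * 0.01)^2)
  expect_lt(abs(gain - gain_true) / gain_true, 0.01)
  expect_equal(attr(y_sin, "transient"), 5)
  expect_error(differentiator_spec(n = 0), "n must be")
  expect_error(differentiator_spec(dt = -0.01), "dt must be")
})

test_that("differentiator converges to the central difference as n shrinks", {
  dt <- 0.01
  t <- seq(0, 8, by = dt)
  x <- sin(2 * pi * 1.2 * t) + 0.3 * cos(2 * pi * 2.5 * t)   # band-limited
  mid <- 300:500
  dx_central <- (x[mid + 1] - x[mid - 1]) / (2 * dt)
  errs <- vapply(c(0.1, 0.05, 0.02, 0.01), function(n) {
    y <- differentiate_gyro(x, differentiator_spec(n = n, dt = dt))
    sqrt(mean((y[mid] - dx_central)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("gravity projection matches the rotation transpose and keeps norm", {
  expect_equal(gravity_in_sensor_frame(c(0, 0, 0)), c(x = 0, y = 0, z = 9.8))
  expect_equal(gravity_in_sensor_frame(c(0, pi / 2, 0)),
               c(x = -9.8, y = 0, z = 9.8 * cos(pi / 2)))
  set.seed(7)
  for (i in 1:1000) {
    pose <- stats::runif(3, -pi, pi)
    gi <- gravity_in_sensor_frame(pose, 9.8)
    expect_lt(abs(sqrt(sum(gi^2)) - 9.8), 1e-12)
    # independent oracle: full rotation-matrix transpose applied to (0,0,g)
    oracle <- crossprod(euler_to_rotation(pose[1], pose[2], pose[3]),
                        c(0, 0, 9.8))
    expect_lt(max(abs(gi - as.numeric(oracle))), 1e-12)
  }
})

test_that("decomposition components always sum to the raw accelerometer signal", {
  # static rest case
  imu <- static_imu(200)
  comp <- decompose_acceleration(imu, matrix(0, imu$n, 3))
  expect_lt(max(abs(comp$tra)), 1e-12)
  expect_lt(max(abs(comp$cen)), 1e-12)
  expect_lt(max(abs(comp$tan)), 1e-12)
  expect_equal(unname(comp$grav[1, ]), c(0, 0, 9.8))
  # conservation on an arbitrary (noisy) record
  sim <- sim_noisy()
  comp2 <- decompose_acceleration(sim$imu, sim$truth$rpy,
                                  sim$truth$params$geometry)
  resid <- comp2$grav + comp2$cen + comp2$tan + comp2$tra + comp2$col - comp2$raw
  expect_lt(max(abs(resid)), 1e-12)
  expect_true(all(comp2$col == 0))
  # length mismatch is an alignment error
  expect_error(decompose_acceleration(sim$imu, sim$truth$rpy[-1, ]),
               "lengths differ")
})

test_that("pure knee rotation at constant rate leaves no translational residue", {
  # sensor circling a fixed knee centre: world acceleration is centripetal
  # only, so with the true pose the translational estimate must vanish
  dt <- 0.01
  t <- seq(0, 6, by = dt)
  rate <- 1.2  # rad/s about sensor x
  roll <- rate * t
  geom <- sensor_geometry(0, -0.05, -0.2)
  gyro <- cbind(rate, 0, 0)[rep(1, length(t)), ]
  rpy <- cbind(roll, 0, 0)
  grav <- gravity_in_sensor_frame(rpy)
  accel <- centrifugal_acceleration(gyro, geom) + grav  # omega_dot = 0
  imu <- imu_series(gyro, accel, matrix(c(1, 0, 0), length(t), 3, byrow = TRUE), dt)
  comp <- decompose_acceleration(imu, rpy, geom)
  keep <- setdiff(seq_along(t), comp$transient)
  expect_lt(max(abs(comp$tra[keep, ])), 1e-6)
})

test_that("translational acceleration is recovered on noiseless gait with true poses", {
  sim <- sim_clean()
  comp <- decompose_acceleration(sim$imu, sim$truth$rpy,
                                 sim$truth$params$geometry)
  keep <- setdiff(seq_along(sim$truth$t), comp$transient)
  err <- comp$tra[keep, ] - sim$components$tra[keep, ]
  expect_lt(max(sqrt(colMeans(err^2))), 0.05)
})
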