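test_that("static tilt initialization inverts the gravity projection", {
  expect_equal(unname(initial_tilt_from_accel(c(0, 0, 9.8))), c(0, 0))
  # 30 degree roll: A = (0, g sin30, g cos30)
  tilt <- initial_tilt_from_accel(c(0, 4.9, 8.4870))
  expect_equal(tilt[["roll"]] * 180 / pi, 30, tolerance = 0.01 / 30)
  tilt2 <- initial_tilt_from_accel(c(-4.9, 0, 8.4870))
  expect_equal(tilt2[["pitch"]] * 180 / pi, 30, tolerance = 0.01 / 30)
  # round-trip property: pose -> gravity -> tilt
  set.seed(3)
  for (i in 1:100) {
    pose <- c(stats::runif(1, -1.4, 1.4), stats::runif(1, -1.4, 1.4), 0)
    tilt <- initial_tilt_from_accel(gravity_in_sensor_frame(pose))
    expect_equal(unname(tilt), pose[1:2], tolerance = 1e-9)
  }
  expect_error(initial_tilt_from_accel(c(0, 0, 0)), "degenerate")
})

test_that("tilt compensation preserves the field norm and reads out yaw", {
  r <- tilt_compensate_and_yaw(c(1, 0, 0), 0, 0)
  expect_equal(unname(r$mag_c), c(1, 0, 0))
  expect_equal(r$yaw, 0)
  expect_equal(tilt_compensate_and_yaw(c(0, 1, 0), 0, 0)$yaw, -pi / 2)
  set.seed(11)
  for (i in 1:200) {
    m <- stats::rnorm(3)
    roll <- stats::runif(1, -pi, pi); pitch <- stats::runif(1, -pi, pi)
    mc <- tilt_compensate_and_yaw(m, roll, pitch)$mag_c
    expect_lt(abs(sqrt(sum(mc^2)) - sqrt(sum(m^2))), 1e-12)
  }
  # full consistency: sensor sees R0' m_world; compensation with the true
  # roll/pitch recovers the true yaw
  for (i in 1:50) {
    pose <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1),
              stats::runif(1, -3, 3))
    m_sensor <- crossprod(euler_to_rotation(pose[1], pose[2], pose[3]),
                          c(1, 0, 0))
    yaw_m <- tilt_compensate_and_yaw(as.numeric(m_sensor), pose[1], pose[2])$yaw
    expect_equal(yaw_m, pose[3], tolerance = 1e-9)
  }
  expect_error(tilt_compensate_and_yaw(c(0, 0, 1), 0, 0), "undefined")
})

test_that("state transition reduces to axis rates at level pose and integrates", {
  w <- c(0.3, -0.2, 0.5)
  out <- state_transition(c(0, 0, 0), w, 0.01)
  expect_equal(as.numeric(out), c(0.003, -0.002, 0.005))
  expect_equal(as.numeric(state_transition(c(0.1, 0.2, 0.3), c(0, 0, 0), 0.01)),
               c(0.1, 0.2, 0.3))
  # constant roll rate integrates to rate * time
  pose <- c(0, 0, 0)
  for (i in 1:100) pose <- state_transition(pose, c(deg(10), 0, 0), 0.01)
  expect_equal(pose[["roll"]] * 180 / pi, 10, tolerance = 0.05 / 10)
  # gimbal guard flags extreme pitch instead of overflowing
  out2 <- state_transition(c(0, deg(89.9), 0), c(0, 1, 0), 0.01)
  expect_true(attr(out2, "gimbal"))
  expect_true(all(is.finite(out2)))
})

test_that("observation model projects gravity and passes yaw through", {
  expect_equal(observation_model(c(0, 0, 0)), c(0, 0, 0, 9.8))
  expect_equal(observation_model(c(0, 0, 1)), c(1, 0, 0, 9.8))
  ob <- observation_model(c(0, deg(30), 0))
  expect_equal(ob, c(0, -4.9, 0, 9.8 * cos(deg(30))), tolerance = 1e-6)
})

test_that("analytic Jacobians match central finite differences", {
  set.seed(19)
  fd_jac <- function(fun, x, eps = 1e-6) {
    vapply(seq_along(x), function(j) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
      (fun(xp) - fun(xm)) / (2 * eps)
    }, numeric(length(fun(x))))
  }
  for (i in 1:200) {
    pose <- c(stats::runif(1, -1.2, 1.2), stats::runif(1, -1.2, 1.2),
              stats::runif(1, -pi, pi))
    gyro <- stats::rnorm(3, sd = 3)
    jac <- compute_jacobians(pose, gyro, 0.01)
    # the internal state order is (yaw, pitch, roll)
    to_state <- function(p) c(p[3], p[2], p[1])
    from_state <- function(x) c(x[3], x[2], x[1])
    f_num <- fd_jac(function(x) {
      as.numeric(state_transition(from_state(x), gyro, 0.01))[c(3, 2, 1)]
    }, to_state(pose))
    h_num <- fd_jac(function(x) observation_model(from_state(x)), to_state(pose))
    expect_lt(max(abs(jac$f - f_num)), 1e-5)
    expect_lt(max(abs(jac$h - h_num)), 1e-5)
    # trivial rows
    expect_equal(jac$h[1, ], c(1, 0, 0))
    if (max(abs(gyro)) < 1e-12) expect_equal(jac$f, diag(3))
  }
  expect_equal(compute_jacobians(c(0.2, -0.1, 0.4), c(0, 0, 0), 0.01)$f, diag(3))
})

test_that("adaptive noise covariances follow the sensor output", {
  p <- noise_tuning_params(a = 0.1, b = 0.01, e = 0.5, f = 0.1, m_bar = 1)
  expect_equal(adaptive_process_noise(c(0, 0, 0), p), diag(rep(0.01, 3)))
  expect_equal(diag(adaptive_process_noise(c(1, 2, 2), p)), rep(0.91, 3))
  # quadratic scaling: (Omega - b) quadruples when omega doubles
  q1 <- adaptive_process_noise(c(0.3, 0.1, -0.2), p)[1, 1] - p$b
  q2 <- adaptive_process_noise(2 * c(0.3, 0.1, -0.2), p)[1, 1] - p$b
  expect_equal(q2, 4 * q1)
  R_rest <- adaptive_observation_noise(c(0, 0, 9.8), mag_sq = 1, p)
  expect_equal(diag(R_rest)[2:4], rep(p$f, 3))
  expect_equal(R_rest[1, 1], p$d)  # |m_c|^2 = m_bar
  R_mov <- adaptive_observation_noise(c(1, 0, 9.8), mag_sq = 1, p)
  expect_equal(R_mov[2, 2], 0.6)   # e * 1 + f
  # negative entries are floored and counted
  R_neg <- adaptive_observation_noise(c(0, 0, 9.8), mag_sq = 0,
                                      noise_tuning_params(c = 1, d = 0.01,
                                                          m_bar = 1))
  expect_equal(R_neg[1, 1], 1e-9)
  expect_equal(attr(R_neg, "floored"), 1L)
  expect_error(noise_tuning_params(b = 0), "b, d, f")
  expect_error(noise_tuning_params(a = -1), "a, c, e")
})

test_that("single filter steps behave in the classical limits", {
  p <- noise_tuning_params(m_bar = 1)
  pose <- c(0.05, -0.02, 0.3)
  P <- diag(c(1e-4, 1e-4, 1e-4))
  gyro <- c(0.2, -0.1, 0.4)
  # zero innovation: update equals prediction
  pred <- state_transition(pose, gyro, 0.01)
  y0 <- observation_model(pred)
  st <- ekf_step(pose, P, y0, gyro, 0.01, p)
  expect_equal(unname(st$pose), as.numeric(pred), tolerance = 1e-12)
  expect_equal(st$V, rep(0, 4))
  # covariance prediction: f = I (zero rates), Q = q I -> P_pred = P + q I
  p_iso <- noise_tuning_params(a = 0, b = 1e-5, m_bar = 1)
  st2 <- ekf_step(c(0, 0, 0), P, observation_model(c(0, 0, 0)), c(0, 0, 0),
                  0.01, p_iso)
  # h rows at the level pose: yaw passthrough, -g for pitch, +g for roll,
  # and a zero row (the z accel is at its maximum), so B = h(P+Q)h' + R gives
  pp <- 1e-4 + 1e-5
  B_expect <- diag(c(pp + p_iso$d, 9.8^2 * pp + p_iso$f,
                     9.8^2 * pp + p_iso$f, p_iso$f))
  expect_equal(diag(st2$B), diag(B_expect), tolerance = 1e-9)
  # huge R: the gain collapses and the state stays at the prediction
  p_hugeR <- noise_tuning_params(d = 0.01 * 1e6, f = 0.05 * 1e6, m_bar = 1)
  y_off <- y0 + c(0.1, 0.5, -0.5, 0.5)
  st3 <- ekf_step(pose, P, y_off, gyro, 0.01, p_hugeR)
  expect_lt(max(abs(unname(st3$pose) - as.numeric(pred))), 1e-4)
  # updated covariance stays symmetric PSD
  expect_lt(max(abs(st$P - t(st$P))), 1e-12)
  expect_gt(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_error(ekf_step(pose, matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1), 3), y0,
                        gyro, 0.01, p), "symmetric")
})

test_that("a long static record is pinned by gravity and the field", {
  imu <- static_imu(6000)  # 60 s
  poses <- run_pose_estimation(imu, calibration_window = 5)
  expect_lt(max(abs(poses$rpy)) * 180 / pi, 0.1)
  # P stays symmetric PSD throughout
  P <- poses$diagnostics$P
  sym_dev <- max(apply(P, 3, function(m) max(abs(m - t(m)))))
  expect_lt(sym_dev, 1e-9)
  min_eig <- min(apply(P, 3, function(m)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)))
  expect_gt(min_eig, -1e-9)
})

test_that("a constant roll rate is tracked to the closed-form angle", {
  imu <- const_roll_imu(10, t_static = 1, t_roll = 2)
  poses <- run_pose_estimation(imu, calibration_window = 1)
  final_roll <- unname(poses$rpy[nrow(poses$rpy), 1]) * 180 / pi
  expect_equal(final_roll, 20, tolerance = 0.2 / 20)
})

test_that("the filter recovers the pose of noiseless synthetic gait", {
  rmse <- pose_rmse_deg(pose_clean(), sim_clean()$truth)
  expect_lt(rmse[2], 2)       # pitch
  expect_lt(rmse[1], 5)       # roll
  expect_lt(rmse[3], 5)       # yaw
})

test_that("sensor noise at MEMS scale inflates the pose error by less than 2x", {
  rmse_clean <- pose_rmse_deg(pose_clean(), sim_clean()$truth)
  sim <- sim_noisy()
  poses <- suppressWarnings(run_pose_estimation(sim$imu, calibration_window = 5))
  rmse_noisy <- pose_rmse_deg(poses, sim$truth)
  expect_lt(rmse_noisy[2], 2)
  expect_lt(rmse_noisy[1], 5)
  expect_lt(rmse_noisy[3], 5)
  expect_lt(max(rmse_noisy / pmax(rmse_clean, 0.5)), 2)
})

test_that("calibration-window validation catches bad records", {
  imu <- static_imu(100)  # 1 s
  expect_error(run_pose_estimation(imu, calibration_window = 5), "exceeds")
  moving <- imu_series(matrix(0.5, 300, 3),
                       matrix(c(0, 0, 9.8), 300, 3, byrow = TRUE),
                       matrix(c(1, 0, 0), 300, 3, byrow = TRUE), 0.01)
  expect_warning(run_pose_estimation(moving, calibration_window = 2),
                 "not static")
})
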