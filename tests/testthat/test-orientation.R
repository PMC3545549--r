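# Initial pose, strapdown integration, and the roll-constraint drift
# correction.

test_that("initial orientation handles the aligned and quarter-turn poses", {
  p <- initial_orientation(c(0, 0, 9.81))
  expect_equal(unclass(p$q0), c(1, 0, 0, 0))
  expect_equal(p$theta0, 0)

  p <- initial_orientation(c(0, 9.81, 0))
  expect_equal(p$theta0, pi / 2, tolerance = 1e-12)
  expect_equal(p$u0[3], 0)
  expect_lt(abs(abs(p$u0[1]) - 1), 1e-9)
  # the measured gravity direction (-a0hat) must map to global -Z
  g_dir <- quat_rotate(p$q0, c(0, -1, 0))
  expect_lt(max(abs(g_dir - c(0, 0, -1))), 1e-6)
})

test_that("initial orientation verticalizes random static readings", {
  set.seed(21)
  for (i in 1:20) {
    q_true <- random_quat()
    # reaction to gravity seen in the sensor frame (oracle: matrix transpose)
    R <- quat_to_matrix(q_true)
    a0 <- as.numeric(t(R) %*% c(0, 0, 9.81))
    pose <- initial_orientation(a0)
    up <- quat_rotate(pose$q0, a0 / sqrt(sum(a0^2)))
    expect_lt(max(abs(up - c(0, 0, 1))), 1e-6)
    expect_equal(pose$u0[3], 0)
    expect_true(pose$theta0 >= 0 && pose$theta0 <= pi)
  }
})

test_that("non-static and null readings are rejected", {
  expect_error(initial_orientation(c(0, 0, 0)), "zero")
  expect_error(initial_orientation(c(0, 0, 5)), "static")
  expect_error(initial_orientation(c(0, 0, 12)), "static")
})

test_that("constant-rate strapdown matches the closed-form rotation", {
  q <- quat_identity()
  for (i in 1:500) q <- update_orientation(q, c(0, 0, pi / 2), 500)
  target <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  expect_lt(quat_angle_between(q, target), 1e-6)
  # zero rate leaves the quaternion unchanged
  q2 <- update_orientation(q, c(0, 0, 0), 500)
  expect_equal(unclass(q2), unclass(q), tolerance = 1e-12)
})

test_that("strapdown of piecewise-constant rates matches matrix exponentials", {
  set.seed(22)
  f <- 200
  q <- quat_identity()
  R <- diag(3)
  for (i in 1:60) {
    w <- stats::rnorm(3, sd = 2)
    q <- update_orientation(q, w, f)
    # body rates compose on the right of the rotation matrix
    R <- R %*% rotmat_axis_angle(w, sqrt(sum(w^2)) / f)
    expect_lt(rotmat_angle(quat_to_matrix(q), R), 1e-6 * i)
  }
})

test_that("integrate_orientation agrees with stepwise update_orientation", {
  set.seed(23)
  gyro <- matrix(stats::rnorm(90, sd = 1), 30, 3)
  q0 <- random_quat()
  series <- integrate_orientation(q0, gyro, 100)
  q <- q0
  for (t in 2:30) {
    q <- update_orientation(q, gyro[t, ], 100)
    expect_lt(quat_angle_between(
      quaternion(series[t, 1], series[t, 2], series[t, 3], series[t, 4]), q),
      1e-9)
  }
})

test_that("halving the step changes the integrated terminal orientation at O(1/f)", {
  omega_fun <- function(t) c(2 * sin(t), 1.5 * cos(2 * t), 0.5 * sin(3 * t))
  terminal <- function(f) {
    ts <- seq(0, 4, by = 1 / f)
    gyro <- t(vapply(ts, omega_fun, numeric(3)))
    q <- integrate_orientation(quat_identity(), gyro, f)
    quaternion(q[nrow(q), 1], q[nrow(q), 2], q[nrow(q), 3], q[nrow(q), 4])
  }
  e1 <- quat_angle_between(terminal(250), terminal(1000))
  e2 <- quat_angle_between(terminal(500), terminal(1000))
  expect_lt(e2, e1)          # finer sampling converges
  expect_lt(e1, 0.02)        # and the error is already small
})

test_that("principal_roll_axis matches the covariance eigenvector oracle", {
  W <- matrix(rep(c(0, 2, 0), 5), ncol = 3, byrow = TRUE) *
    matrix(c(1, -1, 1, -1, 1), 5, 3)
  expect_equal(principal_roll_axis(W), c(0, 1, 0))

  # axis tilted 10 degrees from Y toward Z, 1% orthogonal noise
  set.seed(24)
  axis <- c(0, cos(10 * pi / 180), sin(10 * pi / 180))
  amp <- sin(2 * pi * seq(0, 1, length.out = 200))
  W <- outer(amp, axis) + matrix(stats::rnorm(600, sd = 0.01), 200, 3)
  p <- principal_roll_axis(W)
  expect_lt(acos(min(1, abs(sum(p * axis)))), 0.5 * pi / 180)

  for (i in 1:10) {
    W <- matrix(stats::rnorm(45), 15, 3)
    p <- principal_roll_axis(W)
    e <- eigen(stats::cov(W), symmetric = TRUE)$vectors[, 1]
    expect_lt(min(max(abs(p - e)), max(abs(p + e))), 1e-9)
  }
  expect_error(principal_roll_axis(matrix(0, 10, 3)), "degenerate")
})

test_that("drift correction parameters follow the constraint geometry", {
  c0 <- drift_correction_for_cycle(c(0, 1, 0), 100)
  expect_equal(c0$delta_theta, 0)

  c10 <- drift_correction_for_cycle(c(0, cos(10 * pi / 180), sin(10 * pi / 180)), 100)
  expect_equal(c10$delta_theta, 10 * pi / 180, tolerance = 1e-9)
  expect_lt(min(max(abs(c10$u_axis - c(1, 0, 0))),
                max(abs(c10$u_axis + c(1, 0, 0)))), 1e-9)

  c90 <- drift_correction_for_cycle(c(0, 0, 1), 50)
  expect_equal(c90$delta_theta, pi / 2, tolerance = 1e-9)
  expect_lt(min(max(abs(c90$u_axis - c(1, 0, 0))),
                max(abs(c90$u_axis + c(1, 0, 0)))), 1e-9)
  # corrective axis is always orthogonal to the forward direction
  set.seed(25)
  for (i in 1:10) {
    p <- stats::rnorm(3); p <- p / sqrt(sum(p^2))
    cc <- drift_correction_for_cycle(p, 10)
    expect_lt(abs(cc$u_axis[2]), 1e-9)
  }
})

test_that("corrective quaternion ramps from identity to the full drift angle", {
  corr <- drift_correction_for_cycle(c(0, cos(0.3), sin(0.3)), 200)
  expect_equal(unclass(corrective_quaternion(corr, 1)), c(1, 0, 0, 0))
  q_end <- corrective_quaternion(corr, 200)
  # applied to the cycle's own principal axis it restores the forward axis
  expect_lt(max(abs(quat_rotate(q_end, corr$p_axis) - c(0, 1, 0))), 1e-9)
  # zero drift gives the identity at every sample
  c0 <- drift_correction_for_cycle(c(0, 1, 0), 200)
  expect_equal(unclass(corrective_quaternion(c0, 57)), c(1, 0, 0, 0))
  expect_error(corrective_quaternion(
    drift_correction_for_cycle(c(0, 0, 1), 2), 3))
})

test_that("series correction is a no-op on drift-free data and contracts drift", {
  cfg <- quiet_config(default_scenarios(seed = 31)$elite_t2)
  sim <- simulate_swim(cfg)
  pose <- initial_orientation(colMeans(sim$imu$accel[1:250, ]))
  q_raw <- integrate_orientation(pose$q0, sim$imu$gyro, sim$imu$f)
  cycles <- detect_cycles(sim$imu, q_raw)
  out <- suppressWarnings(correct_orientation_series(q_raw, cycles, sim$imu$gyro))
  n <- sim$imu$n
  for (i in round(seq(1, n, length.out = 20))) {
    expect_lt(quat_angle_between(
      quaternion(out$corrected[i, 1], out$corrected[i, 2],
                 out$corrected[i, 3], out$corrected[i, 4]),
      quaternion(q_raw[i, 1], q_raw[i, 2], q_raw[i, 3], q_raw[i, 4])),
      2e-3)  # drift-free: corrections stay within constraint noise
  }

  # constant gyro bias, mostly about observable (non-forward) directions
  cfgb <- quiet_config(default_scenarios(seed = 31)$elite_t2,
                       gyro_bias = 0.5 * pi / 180 * c(0.77, 0.1, 0.63))
  simb <- simulate_swim(cfgb)
  poseb <- initial_orientation(colMeans(simb$imu$accel[1:250, ]))
  qb <- integrate_orientation(poseb$q0, simb$imu$gyro, simb$imu$f)
  cyc <- detect_cycles(simb$imu, qb)
  outb <- suppressWarnings(correct_orientation_series(qb, cyc, simb$imu$gyro))
  nb <- simb$imu$n
  qt <- unclass(simb$truth$orientation)
  err_raw <- quat_angle_between(
    quaternion(qb[nb, 1], qb[nb, 2], qb[nb, 3], qb[nb, 4]),
    quaternion(qt[nb, 1], qt[nb, 2], qt[nb, 3], qt[nb, 4]))
  err_cor <- quat_angle_between(
    quaternion(outb$corrected[nb, 1], outb$corrected[nb, 2],
               outb$corrected[nb, 3], outb$corrected[nb, 4]),
    quaternion(qt[nb, 1], qt[nb, 2], qt[nb, 3], qt[nb, 4]))
  expect_lt(err_cor, 0.5 * err_raw)

  # applying the correction twice moves the series less than the first pass
  out2 <- suppressWarnings(correct_orientation_series(outb$corrected, cyc,
                                                      simb$imu$gyro))
  d1 <- max(vapply(round(seq(1, nb, length.out = 30)), function(i)
    quat_angle_between(
      quaternion(qb[i, 1], qb[i, 2], qb[i, 3], qb[i, 4]),
      quaternion(outb$corrected[i, 1], outb$corrected[i, 2],
                 outb$corrected[i, 3], outb$corrected[i, 4])), numeric(1)))
  d2 <- max(vapply(round(seq(1, nb, length.out = 30)), function(i)
    quat_angle_between(
      quaternion(outb$corrected[i, 1], outb$corrected[i, 2],
                 outb$corrected[i, 3], outb$corrected[i, 4]),
      quaternion(out2$corrected[i, 1], out2$corrected[i, 2],
                 out2$corrected[i, 3], out2$corrected[i, 4])), numeric(1)))
  expect_lt(d2, d1)
})
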