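# Synthetic front-crawl trial generator: ground-truth swimmer kinematics, an
# IMU sensor model (white noise + bias), and a tethered-cord reference model.
# Every pipeline stage gets a parameter-recovery test from this generator
# without any recorded data.

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}
smoothstep_d <- function(u) {
  inside <- u > 0 & u < 1
  ifelse(inside, 6 * u - 6 * u^2, 0)
}

#' Simulation configuration for a synthetic front-crawl trial
#'
#' Defaults emulate the experimental conditions the estimator is designed
#' for: a 25 m trial starting from a motionless posture in water followed by
#' a push-off, a 500 Hz sacrum IMU, a 100 Hz tethered reference with its
#' pulley 0.72 m above water.
#'
#' @param duration Trial duration (s).
#' @param mean_velocity_segments Matrix or list of `(start_s, v_mean)` rows:
#'   steady swimming regimes; regime changes blend over `transition_s`.
#' @param cycle_freq Stroke-cycle (body-roll) rate (Hz).
#' @param ivv_amplitude Fractional intra-cycle velocity oscillation amplitude.
#' @param roll_amplitude Sacral roll amplitude about the forward axis (rad).
#' @param pitch_yaw_jitter RMS of the slow pitch/yaw wobble (rad).
#' @param gyro_bias Gyroscope bias: scalar magnitude (rad s^-1, spread over a
#'   fixed direction) or a 3-vector.
#' @param gyro_noise_sd Gyroscope white-noise SD per axis (rad s^-1).
#' @param accel_bias Accelerometer bias: scalar magnitude (m s^-2) or a
#'   3-vector.
#' @param accel_noise_sd Accelerometer white-noise SD per axis (m s^-2).
#' @param mount_tilt Constant sensor mounting tilt about the sensor x axis
#'   (rad); exercises the static initial-orientation step.
#' @param bob_vertical,bob_lateral Amplitudes of the small vertical (at twice
#'   the cycle rate) and lateral (at the cycle rate) body-acceleration
#'   oscillations (m s^-2).
#' @param f_imu IMU sampling rate (Hz).
#' @param f_ref Reference sampling rate (Hz).
#' @param pulley_height Reference pulley height above water (m).
#' @param start_offset Initial horizontal distance of the sacrum from the
#'   pulley base (m).
#' @param hold_s Motionless hold at the start of the recording (s), before
#'   the push-off; gives the estimator its static initialization window.
#' @param ramp_s Push-off ramp length following the hold (s).
#' @param transition_s Blend time between mean-velocity regimes (s).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return A `swim_sim_config` list.
#' @export
swim_sim_config <- function(duration = 18,
                            mean_velocity_segments = cbind(0, 1.4),
                            cycle_freq = 0.85,
                            ivv_amplitude = 0.16,
                            roll_amplitude = 0.6,
                            pitch_yaw_jitter = 0.035,
                            gyro_bias = 0.0087,
                            gyro_noise_sd = 0.0087,
                            accel_bias = 0.02,
                            accel_noise_sd = 0.05,
                            mount_tilt = 0.10,
                            bob_vertical = 0.3,
                            bob_lateral = 0.2,
                            f_imu = 500,
                            f_ref = 100,
                            pulley_height = 0.72,
                            start_offset = 0.5,
                            hold_s = 1,
                            ramp_s = 2,
                            transition_s = 1,
                            seed = 1L) {
  seg <- if (is.list(mean_velocity_segments))
    do.call(rbind, mean_velocity_segments) else as.matrix(mean_velocity_segments)
  stopifnot(ncol(seg) == 2, seg[1, 1] == 0, all(diff(seg[, 1]) > 0),
            all(seg[, 2] > 0), duration > 0, cycle_freq > 0,
            duration * cycle_freq >= 2,
            ivv_amplitude >= 0, roll_amplitude >= 0, pitch_yaw_jitter >= 0,
            gyro_noise_sd >= 0, accel_noise_sd >= 0,
            f_imu > 0, f_ref > 0, pulley_height >= 0, start_offset >= 0,
            hold_s >= 0)
  as3 <- function(b, dir) if (length(b) == 3) as.numeric(b) else b * dir
  structure(list(
    duration = duration, mean_velocity_segments = seg,
    cycle_freq = cycle_freq, ivv_amplitude = ivv_amplitude,
    roll_amplitude = roll_amplitude, pitch_yaw_jitter = pitch_yaw_jitter,
    gyro_bias = as3(gyro_bias, c(0.62, -0.50, 0.60)),
    gyro_noise_sd = gyro_noise_sd,
    accel_bias = as3(accel_bias, c(0.30, 0.90, -0.31)),
    accel_noise_sd = accel_noise_sd,
    mount_tilt = mount_tilt,
    bob_vertical = bob_vertical, bob_lateral = bob_lateral,
    f_imu = f_imu, f_ref = f_ref, pulley_height = pulley_height,
    start_offset = start_offset, hold_s = hold_s, ramp_s = ramp_s,
    transition_s = transition_s, seed = as.integer(seed)
  ), class = "swim_sim_config")
}

# Smoothly blended piecewise-constant regime velocity and its derivative.
regime_velocity <- function(t, seg, w) {
  v <- rep(seg[1, 2], length(t))
  dv <- rep(0, length(t))
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    u <- (t - seg[i, 1]) / w
    step <- seg[i, 2] - seg[i - 1, 2]
    v <- v + step * smoothstep(u)
    dv <- dv + step * smoothstep_d(u) / w
  }
  list(v = v, dv = dv)
}

#' Simulate a front-crawl trial with IMU and tethered reference
#'
#' The forward velocity is a per-regime mean shaped by a smooth push-off ramp
#' plus an intra-cycle oscillation placed mainly at twice the body-roll rate
#' (two arm pulls per roll cycle) with a smaller component at the roll rate.
#' Orientation combines the sacral roll about the forward axis, slow filtered
#' pitch/yaw wobble, and a constant mounting tilt. The gyroscope outputs the
#' exact per-sample orientation increments scaled to rates (a standard
#' discretization of body rates) plus bias and white noise; the accelerometer
#' outputs the sensor-frame specific force plus bias and white noise. The
#' reference records the cord length from an elevated pulley at `f_ref`.
#'
#' @param config A [swim_sim_config()].
#' @return List with `truth` (a `swim_truth`: position, velocity, forward
#'   acceleration, orientation series, sensor-frame rates, cycle boundaries),
#'   `imu` (an [imu_recording()]), `ref` (a [reference_recording()]),
#'   `trial` (a [trial_info()] whose pool length is the distance actually
#'   travelled), and `config`.
#' @export
simulate_swim <- function(config) {
  stopifnot(inherits(config, "swim_sim_config"))
  set.seed(config$seed)
  f <- config$f_imu
  n <- round(config$duration * f) + 1L
  t <- (seq_len(n) - 1) / f
  fc <- config$cycle_freq

  # --- true forward velocity and acceleration (analytic) --------------------
  R <- smoothstep((t - config$hold_s) / config$ramp_s)
  dR <- smoothstep_d((t - config$hold_s) / config$ramp_s) / config$ramp_s
  reg <- regime_velocity(t, config$mean_velocity_segments, config$transition_s)
  osc <- 0.7 * sin(4 * pi * fc * t) + 0.3 * sin(2 * pi * fc * t)
  dosc <- 0.7 * 4 * pi * fc * cos(4 * pi * fc * t) +
          0.3 * 2 * pi * fc * cos(2 * pi * fc * t)
  a_iv <- config$ivv_amplitude
  v <- R * reg$v * (1 + a_iv * osc)
  dv <- dR * reg$v * (1 + a_iv * osc) + R * reg$dv * (1 + a_iv * osc) +
        R * reg$v * a_iv * dosc
  x <- config$start_offset + pracma::cumtrapz(v)[, 1] / f

  # --- true orientation -----------------------------------------------------
  roll <- config$roll_amplitude * R * sin(2 * pi * fc * t)
  jitter <- function() {
    if (config$pitch_yaw_jitter == 0) return(numeric(n))
    w <- lowpass_zerophase(stats::rnorm(n), f, 1)
    config$pitch_yaw_jitter * R * w / stats::sd(w)
  }
  pitch <- jitter(); yaw <- jitter()
  half <- function(a) cbind(cos(a / 2), sin(a / 2))
  hr <- half(roll); hp <- half(pitch); hy <- half(yaw)
  Q_roll  <- cbind(hr[, 1], 0, hr[, 2], 0)          # about global Y
  Q_pitch <- cbind(hp[, 1], hp[, 2], 0, 0)          # about X
  Q_yaw   <- cbind(hy[, 1], 0, 0, hy[, 2])          # about Z
  q_mount <- as.numeric(quat_from_axis_angle(c(1, 0, 0), config$mount_tilt))
  Q_mount <- matrix(q_mount, n, 4, byrow = TRUE)
  Q <- quat_multiply_rows(
    quat_multiply_rows(quat_multiply_rows(Q_roll, Q_pitch), Q_yaw), Q_mount)
  Q <- quat_normalize_rows(Q)

  # --- sensor-frame body rates from exact orientation increments ------------
  Qc <- cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
  Dq <- quat_multiply_rows(Qc[-n, , drop = FALSE], Q[-1, , drop = FALSE])
  sgn <- sign(Dq[, 1] + (Dq[, 1] == 0))
  Dq <- Dq * sgn
  ang <- 2 * acos(pmin(1, Dq[, 1]))
  vn <- sqrt(rowSums(Dq[, 2:4, drop = FALSE]^2))
  scale <- ifelse(vn > 0, ang / vn, 0) * f
  omega_sf <- rbind(c(0, 0, 0), Dq[, 2:4, drop = FALSE] * scale)

  # --- accelerometer: sensor-frame specific force ---------------------------
  bob_y <- config$bob_vertical * R * sin(4 * pi * fc * t + 0.8)
  bob_x <- config$bob_lateral * R * sin(2 * pi * fc * t + 1.9)
  sf_gf <- cbind(bob_x, dv, bob_y + GRAVITY_DEFAULT)  # a_body - g, global frame
  accel_sf <- quat_rotate_rows(Qc, sf_gf)

  # --- sensor imperfections -------------------------------------------------
  gyro <- omega_sf +
    matrix(config$gyro_bias, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, sd = config$gyro_noise_sd), n, 3)
  accel <- accel_sf +
    matrix(config$accel_bias, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, sd = config$accel_noise_sd), n, 3)

  # --- true cycle boundaries (upward zero crossings of the roll rate) -------
  droll <- c(0, diff(roll)) * f
  bnd <- which(droll[-n] < 0 & droll[-1] >= 0) + 1L
  bnd <- bnd[c(TRUE, diff(bnd) > 0.4 * f)]

  # --- tethered reference ---------------------------------------------------
  n_ref <- floor((n - 1) * config$f_ref / f) + 1L
  t_ref <- (seq_len(n_ref) - 1) / config$f_ref
  x_ref <- stats::approx(t, x, xout = t_ref, rule = 2)$y
  cord <- sqrt(x_ref^2 + config$pulley_height^2)

  truth <- structure(list(
    t = t, position = x, velocity = v, accel_forward = dv,
    orientation = orientation_series(Q, f), omega_sf = omega_sf,
    cycle_boundaries = bnd, f = f
  ), class = "swim_truth")

  list(
    truth = truth,
    imu = imu_recording(accel, gyro, f = f, t = t),
    ref = reference_recording(cord, f_ref = config$f_ref,
                              pulley_height = config$pulley_height, t = t_ref),
    trial = trial_info(pool_length = x[n] - x[1],
                       duration = (n - 1) / f),
    config = config
  )
}

#' Preset study conditions
#'
#' Eight presets mirroring a four-trial incremental protocol (70 to 100% of a
#' group-typical best 100 m velocity) for an elite group (V100 = 1.68 m/s,
#' lower intra-cycle variation) and a recreational group (V100 = 1.34 m/s,
#' higher intra-cycle variation) over a 25 m pool. Stroke rate rises with
#' target velocity within 0.5-1 Hz.
#'
#' @param seed Base RNG seed stored in each preset.
#' @return Named list of [swim_sim_config()]s: `elite_t1..t4`,
#'   `recreational_t1..t4`.
#' @export
default_scenarios <- function(seed = 1L) {
  make <- function(v100, frac, ivv_amp, seed_off) {
    v <- v100 * frac
    swim_sim_config(
      duration = round(25 / v + 2, 1),   # hold + half the push-off ramp
      mean_velocity_segments = cbind(0, v),
      cycle_freq = min(1, max(0.5, 0.35 + 0.35 * v)),
      ivv_amplitude = ivv_amp,
      seed = seed + seed_off
    )
  }
  fr <- c(0.7, 0.8, 0.9, 1.0)
  out <- c(
    stats::setNames(lapply(1:4, function(i) make(1.68, fr[i], 0.14, i)),
                    paste0("elite_t", 1:4)),
    stats::setNames(lapply(1:4, function(i) make(1.34, fr[i], 0.20, i + 4L)),
                    paste0("recreational_t", 1:4))
  )
  out
}
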