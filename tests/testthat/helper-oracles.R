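# Shared oracles and fixture builders. Oracles are kept independent of the
# implementation paths they check: rotations via explicit 3x3 matrices,
# statistics via direct summation.

# rotation matrix for an axis-angle rotation (Rodrigues form)
rotmat_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# random unit quaternion
random_quat <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion(q[1], q[2], q[3], q[4])
}

# angle between two rotation matrices
rotmat_angle <- function(R1, R2) {
  acos(min(1, max(-1, (sum(diag(t(R1) %*% R2)) - 1) / 2)))
}

# noise-free copy of a simulation config
quiet_config <- function(cfg, ...) {
  args <- list(duration = cfg$duration,
               mean_velocity_segments = cfg$mean_velocity_segments,
               cycle_freq = cfg$cycle_freq,
               ivv_amplitude = cfg$ivv_amplitude,
               pitch_yaw_jitter = 0, gyro_bias = 0, gyro_noise_sd = 0,
               accel_bias = 0, accel_noise_sd = 0, seed = cfg$seed)
  do.call(swim_sim_config, utils::modifyList(args, list(...)))
}

# run the estimation pipeline quietly
estimate_quiet <- function(sim, config = run_config()) {
  suppressWarnings(suppressMessages(
    estimate_velocity(sim$imu, sim$trial, config)))
}

# cycle set over a uniform grid: n_cycles cycles of len samples each
uniform_cycles <- function(n_cycles, len, f) {
  cycle_set(seq(1L, by = as.integer(len), length.out = n_cycles + 1L), f)
}
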