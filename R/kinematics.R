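# Stroke-cycle detection, forward acceleration in the global frame, and
# trapezoidal integration to (raw, drifting) forward velocity.

#' IMU recording container
#'
#' @param accel n x 3 accelerometer matrix (m s^-2, sensor frame).
#' @param gyro n x 3 gyroscope matrix (rad s^-1, sensor frame).
#' @param f Sampling rate (Hz); 500 Hz in the experimental setup emulated
#'   here, other rates allowed.
#' @param t Optional time stamps (s); defaults to a uniform grid starting at
#'   0. Uniformity is validated to 1e-6 s.
#' @return An `imu_recording` list.
#' @export
imu_recording <- function(accel, gyro, f = 500, t = NULL) {
  stopifnot(is.matrix(accel), is.matrix(gyro),
            ncol(accel) == 3, ncol(gyro) == 3,
            nrow(accel) == nrow(gyro), f > 0)
  n <- nrow(accel)
  if (is.null(t)) t <- (seq_len(n) - 1) / f
  stopifnot(length(t) == n)
  if (n > 1 && max(abs(diff(t) - 1 / f)) > 1e-6) {
    stop("non-uniform sampling: time stamps deviate from 1/f by more than 1e-6 s")
  }
  structure(list(t = t, accel = accel, gyro = gyro, f = f, n = n),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("imu_recording: %d samples at %g Hz (%.2f s)\n",
              x$n, x$f, x$n / x$f))
  invisible(x)
}

#' Stroke-cycle set
#'
#' @param boundaries Strictly increasing sample indices `C_1 < C_2 < ...`;
#'   cycle k covers samples `[C_k, C_{k+1})`.
#' @param f Sampling rate (Hz) of the underlying series.
#' @return A `cycle_set` with per-cycle sample counts `n_samples` and cycle
#'   frequencies `f_cycle = f / n_samples`.
#' @export
cycle_set <- function(boundaries, f) {
  boundaries <- as.integer(boundaries)
  stopifnot(length(boundaries) >= 2, all(diff(boundaries) > 0), f > 0)
  n_samples <- diff(boundaries)
  structure(list(boundaries = boundaries,
                 n_cycles = length(boundaries) - 1L,
                 n_samples = n_samples,
                 f_cycle = f / n_samples,
                 f = f),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("cycle_set: %d cycles, mean period %.2f s (%.2f-%.2f s)\n",
              x$n_cycles, mean(x$n_samples) / x$f,
              min(x$n_samples) / x$f, max(x$n_samples) / x$f))
  invisible(x)
}

# sample index ranges of cycle k
cycle_range <- function(cycles, k) {
  cycles$boundaries[k]:(cycles$boundaries[k + 1L] - 1L)
}

#' Detect stroke cycles from the body-roll angular velocity
#'
#' One front-crawl stroke cycle is one full body-roll period. The global-frame
#' angular velocity about the swimming direction (the roll rate) is low-pass
#' filtered and cycle boundaries are placed at its successive upward zero
#' crossings; a refractory period suppresses chatter near the crossings.
#'
#' @param recording An [imu_recording()].
#' @param orientation An `orientation_series` for the same samples (the
#'   uncorrected strapdown series is fine: cycle timing is insensitive to
#'   slow drift).
#' @param cutoff_hz Low-pass cutoff for the roll-rate signal (Hz).
#' @param refractory_s Minimum spacing between boundaries (s); also the
#'   physiological floor for a stroke-cycle period.
#' @param max_period_s Physiological ceiling for a cycle period (s); longer
#'   intervals are flagged with a warning.
#' @return A [cycle_set()].
#' @export
detect_cycles <- function(recording, orientation, cutoff_hz = 3,
                          refractory_s = 0.4, max_period_s = 5) {
  f <- recording$f
  if (recording$n < 2 * f) stop("need at least 2 s of data to detect cycles")
  omega_gf <- quat_rotate_rows(unclass(orientation), recording$gyro)
  roll <- lowpass_zerophase(omega_gf[, 2], f, cutoff_hz)
  if (max(abs(roll)) < 1e-9) stop("no cycles: roll angular velocity is null")
  up <- which(roll[-length(roll)] < 0 & roll[-1] >= 0) + 1L
  # hysteresis: a crossing only counts if genuine rolling follows it; filter
  # ringing around the onset and sensor noise during still phases otherwise
  # produce micro-crossings
  amp_floor <- 0.1 * stats::quantile(abs(roll), 0.9)
  up <- up[vapply(up, function(i) {
    max(abs(roll[i:min(length(roll), i + round(refractory_s * f))])) >= amp_floor
  }, logical(1))]
  if (length(up) >= 2) {
    keep <- up[1]
    for (i in up[-1]) if (i - keep[length(keep)] >= refractory_s * f) keep <- c(keep, i)
    up <- keep
  }
  if (length(up) < 3) stop("no cycles: fewer than 2 full roll periods detected")
  if (any(diff(up) > max_period_s * f)) {
    warning("cycle period exceeds the physiological ceiling; check the recording")
  }
  cycle_set(up, f)
}

#' Forward acceleration in the global frame
#'
#' Rotates each accelerometer sample to the global frame with the (corrected)
#' orientation, removes the gravity reaction, and projects onto the swimming
#' direction `[0, 1, 0]`.
#'
#' @param recording An [imu_recording()].
#' @param corrected An `orientation_series` (drift-corrected).
#' @param gravity Gravity magnitude (m s^-2).
#' @return Numeric vector of forward acceleration (m s^-2).
#' @export
forward_acceleration <- function(recording, corrected, gravity = GRAVITY_DEFAULT) {
  stopifnot(nrow(corrected) == recording$n)
  a_gf <- quat_rotate_rows(unclass(corrected), recording$accel)
  a_gf[, 2]   # gravity is vertical; the Y projection removes it identically
}

#' Trapezoidal integration of forward acceleration to velocity
#'
#' @param a_forward Forward acceleration series (m s^-2).
#' @param f Sampling rate (Hz).
#' @param v0 Initial velocity (m s^-1); 0 for a motionless start.
#' @return Velocity series (m s^-1), same length.
#' @export
integrate_velocity <- function(a_forward, f, v0 = 0) {
  stopifnot(f > 0)
  v0 + pracma::cumtrapz(as.numeric(a_forward))[, 1] / f
}

#' Per-cycle mean velocity
#'
#' @param v Velocity series (m s^-1).
#' @param cycles A [cycle_set()] within the bounds of `v`.
#' @return Numeric vector of cycle means (m s^-1), one per cycle.
#' @export
cycle_means <- function(v, cycles) {
  if (max(cycles$boundaries) - 1L > length(v)) {
    stop("cycle boundaries exceed the velocity series")
  }
  vapply(seq_len(cycles$n_cycles),
         function(k) mean(v[cycle_range(cycles, k)]), numeric(1))
}

#' Velocity profile container
#'
#' @param v Forward velocity series (m s^-1).
#' @param f Sampling rate (Hz).
#' @param cycles Optional [cycle_set()]; when given, per-cycle means are
#'   attached.
#' @return A `velocity_profile` list with `v`, `f`, `t`, and `cycle_means`.
#' @export
velocity_profile <- function(v, f, cycles = NULL) {
  structure(list(v = as.numeric(v), f = f, t = (seq_along(v) - 1) / f,
                 cycles = cycles,
                 cycle_means = if (!is.null(cycles)) cycle_means(v, cycles)),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("velocity_profile: %d samples at %g Hz, mean %.3f m/s",
              length(x$v), x$f, mean(x$v)))
  if (!is.null(x$cycle_means)) {
    cat(sprintf(", %d cycles (cycle means %.2f-%.2f m/s)",
                length(x$cycle_means), min(x$cycle_means), max(x$cycle_means)))
  }
  cat("\n")
  invisible(x)
}
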