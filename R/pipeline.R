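# End-to-end orchestration: IMU recording -> drift-corrected orientation ->
# forward acceleration -> velocity -> de-drifted, mean-anchored velocity
# profile; and comparison of an estimate against the tethered reference.

#' Run configuration for the estimation pipeline
#'
#' Defaults follow the experimental setup the method targets: 500 Hz IMU,
#' 100 Hz reference, GMA threshold 20% of the forward-acceleration variance,
#' 25 m pool, pulley 0.72 m above water.
#'
#' @param gravity Gravity magnitude (m s^-2).
#' @param gma_threshold GMA variance-change threshold (fraction of total
#'   variance).
#' @param gma_lambda GMA forgetting factor.
#' @param cycle_cutoff_hz Low-pass cutoff for cycle detection (Hz).
#' @param cycle_refractory_s Refractory period between cycle boundaries (s).
#' @param static_window_s Length of the motionless start window used for the
#'   initial orientation (s).
#' @param static_sd_g Maximum accelerometer-norm SD (in units of g) for the
#'   start window to count as static.
#' @param static_gyro_rad Maximum mean angular rate (rad s^-1) in the start
#'   window; a rolling start cannot initialize the orientation.
#' @param compare_rate_hz Common rate for instantaneous comparison (Hz).
#' @param v0 Initial velocity (m s^-1).
#' @return A `run_config` list.
#' @export
run_config <- function(gravity = GRAVITY_DEFAULT,
                       gma_threshold = 0.20,
                       gma_lambda = 0.999,
                       cycle_cutoff_hz = 3,
                       cycle_refractory_s = 0.4,
                       static_window_s = 0.5,
                       static_sd_g = 0.05,
                       static_gyro_rad = 0.1,
                       compare_rate_hz = 100,
                       v0 = 0) {
  structure(list(gravity = gravity, gma_threshold = gma_threshold,
                 gma_lambda = gma_lambda, cycle_cutoff_hz = cycle_cutoff_hz,
                 cycle_refractory_s = cycle_refractory_s,
                 static_window_s = static_window_s, static_sd_g = static_sd_g,
                 static_gyro_rad = static_gyro_rad,
                 compare_rate_hz = compare_rate_hz, v0 = v0),
            class = "run_config")
}

#' Estimate the forward-velocity profile from a single IMU recording
#'
#' Runs the full chain: static initial orientation, strapdown gyroscope
#' integration, stroke-cycle detection from the roll rate, per-cycle drift
#' correction under the roll constraint, forward-acceleration extraction,
#' trapezoidal integration, GMA segmentation, peak-envelope spline
#' detrending, and anchoring to the trial mean velocity.
#'
#' @param recording An [imu_recording()].
#' @param trial A [trial_info()] (pool length and trial duration).
#' @param config A [run_config()].
#' @return A `velocity_estimate` list: `profile` ([velocity_profile()] with
#'   cycle means), `cycles`, `segments`, `orientation` (corrected series),
#'   `raw_velocity`, `trend`, and `diagnostics` (per-cycle drift angles in
#'   radians, static-window statistics, resolved configuration).
#' @export
estimate_velocity <- function(recording, trial, config = run_config()) {
  stopifnot(inherits(recording, "imu_recording"), inherits(trial, "trial_info"))
  f <- recording$f

  # 1. static start window -> initial orientation
  win <- seq_len(max(2L, round(config$static_window_s * f)))
  norms <- sqrt(rowSums(recording$accel[win, , drop = FALSE]^2))
  static_sd <- stats::sd(norms) / config$gravity
  if (static_sd > config$static_sd_g) {
    stop(sprintf(
      "initial-orientation: start window is not static (accel-norm SD %.3f g > %.3f g)",
      static_sd, config$static_sd_g))
  }
  mean_rate <- mean(sqrt(rowSums(recording$gyro[win, , drop = FALSE]^2)))
  if (mean_rate > config$static_gyro_rad) {
    stop(sprintf(
      "initial-orientation: start window is not static (mean angular rate %.2f rad/s > %.2f rad/s)",
      mean_rate, config$static_gyro_rad))
  }
  a0 <- colMeans(recording$accel[win, , drop = FALSE])
  pose <- initial_orientation(a0, gravity = config$gravity)

  # 2. strapdown integration
  q_raw <- integrate_orientation(pose$q0, recording$gyro, f)

  # 3. stroke cycles from the roll rate
  cycles <- detect_cycles(recording, q_raw,
                          cutoff_hz = config$cycle_cutoff_hz,
                          refractory_s = config$cycle_refractory_s)

  # 4. per-cycle drift correction
  corr <- correct_orientation_series(q_raw, cycles, recording$gyro)

  # 5. forward acceleration and raw velocity
  a_fwd <- forward_acceleration(recording, corr$corrected,
                                gravity = config$gravity)
  v_raw <- integrate_velocity(a_fwd, f, v0 = config$v0)

  # 6. segmentation and detrending
  segments <- gma_segment(a_fwd, threshold_frac = config$gma_threshold,
                          lambda = config$gma_lambda,
                          min_len = round(stats::median(cycles$n_samples)))
  trend <- fit_trend(v_raw, segments, cycles)
  profile <- detrend_velocity(v_raw, trend, trial, f, cycles)

  structure(list(
    profile = profile, cycles = cycles, segments = segments,
    orientation = corr$corrected, uncorrected_orientation = q_raw,
    raw_velocity = v_raw, forward_accel = a_fwd, trend = trend,
    diagnostics = list(
      initial_pose = pose,
      static_sd_g = static_sd,
      drift_angles = vapply(corr$corrections, `[[`, numeric(1), "delta_theta"),
      segment_starts = segments$segments[, "start"],
      config = config, trial = trial
    )
  ), class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat("velocity_estimate\n")
  print(x$profile)
  print(x$cycles)
  print(x$segments)
  cat(sprintf("  drift angles: median %.2f deg (max %.2f deg)\n",
              stats::median(x$diagnostics$drift_angles) * 180 / pi,
              max(x$diagnostics$drift_angles) * 180 / pi))
  invisible(x)
}

#' Time-align two velocity series by cross-correlation
#'
#' @param v_est,v_ref Series at a common rate.
#' @param f Common sampling rate (Hz).
#' @param max_lag_s Maximum |lag| searched (s).
#' @param min_corr Minimum peak correlation accepted.
#' @return List `est`, `ref` (trimmed to overlap), `lag` (samples; positive
#'   means the estimate leads), `corr` (peak correlation).
#' @export
align_series <- function(v_est, v_ref, f, max_lag_s = 2, min_corr = 0.2) {
  nl <- min(round(max_lag_s * f), min(length(v_est), length(v_ref)) %/% 2L)
  lags <- -nl:nl
  # correlation normalized over each lag's actual overlap (a fixed-n
  # normalization biases the estimate toward small lags)
  cors <- vapply(lags, function(k) {
    if (k >= 0) {
      m <- min(length(v_est) - k, length(v_ref))
      stats::cor(v_est[(k + 1):(k + m)], v_ref[1:m])
    } else {
      m <- min(length(v_ref) + k, length(v_est))
      stats::cor(v_est[1:m], v_ref[(-k + 1):(-k + m)])
    }
  }, numeric(1))
  i <- which.max(cors)
  lag <- lags[i]
  if (cors[i] < min_corr) {
    stop(sprintf("alignment failed: peak cross-correlation %.2f below %.2f",
                 cors[i], min_corr))
  }
  # positive lag: the estimate lags the reference; drop its leading samples.
  if (lag >= 0) {
    m <- min(length(v_est) - lag, length(v_ref))
    est <- v_est[(lag + 1):(lag + m)]; ref <- v_ref[1:m]
  } else {
    m <- min(length(v_ref) + lag, length(v_est))
    est <- v_est[1:m]; ref <- v_ref[(-lag + 1):(-lag + m)]
  }
  list(est = est, ref = ref, lag = lag, corr = cors[i])
}

#' Compare an IMU velocity estimate against the tethered reference
#'
#' Parallax-corrects the reference cord record, resamples the estimate to the
#' comparison rate, time-aligns the two by cross-correlation, and computes
#' the full set of agreement statistics: cycle-mean bias/precision, limits of
#' agreement, Spearman rho, nPVI, heteroscedasticity screen, instantaneous
#' RMS/max/relative errors, and IVV from both systems.
#'
#' @param est A `velocity_estimate` from [estimate_velocity()].
#' @param ref A [reference_recording()].
#' @param config A [run_config()].
#' @return An [agreement_report()].
#' @export
compare_runs <- function(est, ref, config = run_config()) {
  stopifnot(inherits(est, "velocity_estimate"),
            inherits(ref, "reference_recording"))
  fcmp <- config$compare_rate_hz
  v_ref <- parallax_correct(ref)
  if (ref$f_ref != fcmp) v_ref <- resample_to(v_ref, ref$f_ref, fcmp)
  v_est <- resample_to(est$profile$v, est$profile$f, fcmp)
  al <- align_series(v_est, v_ref, fcmp)

  # map cycle boundaries onto the comparison grid (account for the lag trim)
  scale <- fcmp / est$profile$f
  b <- round((est$cycles$boundaries - 1) * scale) + 1L
  if (al$lag >= 0) b <- b - al$lag
  m <- length(al$est)
  b <- unique(pmin(pmax(b, 1L), m))
  if (length(b) < 3) stop("too few cycles remain after alignment")
  cyc <- cycle_set(b, fcmp)
  est_means <- cycle_means(al$est, cyc)
  ref_means <- cycle_means(al$ref, cyc)

  agreement_report(
    ref_means, est_means, v_est = al$est, v_ref = al$ref,
    extra = list(
      ivv_est = ivv(al$est, cyc)$ivv,
      ivv_ref = ivv(al$ref, cyc)$ivv,
      lag_samples = al$lag,
      align_corr = al$corr
    )
  )
}
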