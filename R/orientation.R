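# Orientation tracking: initial pose from a static accelerometer reading,
# strapdown gyroscope integration, and per-stroke-cycle drift correction from
# the biomechanical constraint that the sacrum rolls on average about the
# swimming direction (global Y).
#
# Frames: global frame GF has Y along the swimming direction and Z vertically
# up. Quaternions map SF -> GF (see quaternion.R for conventions). The
# accelerometer measures specific force, so at rest it reads the *reaction* to
# gravity: an upright sensor reports approximately c(0, 0, +g).

GRAVITY_DEFAULT <- 9.81

.Y_GF <- c(0, 1, 0)
.Z_GF <- c(0, 0, 1)

#' Initial orientation from a static accelerometer reading
#'
#' At the motionless start of a trial the accelerometer reading has magnitude
#' close to standard gravity and encodes the sensor's inclination. The initial
#' quaternion rotates the measured (normalized) gravity reaction onto global
#' +Z through the smallest angle, about a horizontal axis; the start azimuth is
#' taken as zero (no magnetometer), which defines global Y up to the roll
#' constraint applied later.
#'
#' @param a0 Static accelerometer reading, sensor frame, 3-vector (m s^-2).
#' @param gravity Gravity magnitude (m s^-2).
#' @param tol_frac Maximum allowed relative deviation of `|a0|` from
#'   `gravity` before the reading is rejected as non-static.
#' @return A `static_pose` list: `q0` (unit quaternion SF->GF), `theta0`
#'   (initial inclination, rad), `u0` (horizontal rotation axis, zero third
#'   component; the zero vector when already aligned).
#' @export
initial_orientation <- function(a0, gravity = GRAVITY_DEFAULT, tol_frac = 0.15) {
  stopifnot(length(a0) == 3, all(is.finite(a0)))
  nrm <- sqrt(sum(a0^2))
  if (nrm == 0) stop("static accelerometer reading is the zero vector")
  if (abs(nrm - gravity) > tol_frac * gravity) {
    stop(sprintf(
      "static reading magnitude %.3f deviates more than %.0f%% from gravity %.3f: sensor not static",
      nrm, 100 * tol_frac, gravity))
  }
  ahat <- a0 / nrm
  cth <- max(-1, min(1, sum(ahat * .Z_GF)))
  theta0 <- acos(cth)
  u0 <- pracma::cross(ahat, .Z_GF)      # = c(a0y, -a0x, 0) / |a0|: horizontal
  if (sqrt(sum(u0^2)) < 1e-12) {
    # already aligned (theta0 = 0) or exactly inverted (theta0 = pi): for the
    # inverted case any horizontal axis works, pick X.
    q0 <- if (theta0 < pi / 2) quat_identity() else
      quat_from_axis_angle(c(1, 0, 0), theta0)
    u0 <- c(0, 0, 0)
  } else {
    q0 <- quat_from_axis_angle(u0, theta0)
  }
  structure(list(q0 = q0, theta0 = theta0, u0 = u0), class = "static_pose")
}

#' Single strapdown orientation update
#'
#' Advances the SF->GF quaternion by one sample using the gyroscope rate held
#' constant over the sampling interval: the axis-angle increment has angle
#' `|omega| / f` about `omega`. Body rates compose on the sensor side; the
#' result is renormalized so norm error cannot accumulate at 500 Hz.
#'
#' @param q_prev Unit quaternion at the previous sample.
#' @param omega Angular velocity, sensor frame (rad s^-1), 3-vector.
#' @param f Sampling rate (Hz).
#' @return Updated unit quaternion.
#' @export
update_orientation <- function(q_prev, omega, f) {
  stopifnot(f > 0, length(omega) == 3)
  ang <- sqrt(sum(omega^2)) / f
  dq <- if (ang == 0) quat_identity() else quat_from_axis_angle(omega, ang)
  quat_normalize(quat_multiply(q_prev, dq))
}

#' Strapdown integration of a gyroscope series
#'
#' Runs [update_orientation()] across a whole recording, starting from `q0`.
#' Sample 1 carries `q0`; sample t integrates the rate at sample t over
#' `1/f` seconds.
#'
#' @param q0 Initial unit quaternion (e.g. from [initial_orientation()]).
#' @param gyro n x 3 matrix of angular velocity, sensor frame (rad s^-1).
#' @param f Sampling rate (Hz).
#' @return An `orientation_series`: n x 4 matrix of unit quaternions with
#'   attribute `f`.
#' @export
integrate_orientation <- function(q0, gyro, f) {
  stopifnot(is.matrix(gyro), ncol(gyro) == 3, f > 0)
  n <- nrow(gyro)
  # precompute all increment quaternions vectorized
  ang <- sqrt(rowSums(gyro^2)) / f
  half <- ang / 2
  s <- ifelse(ang > 0, sin(half) / pmax(ang, .Machine$double.xmin), 0) / f
  Dq <- cbind(cos(half), gyro * s)
  Q <- matrix(0, n, 4)
  q <- as.numeric(q0)
  Q[1, ] <- q
  for (t in seq_len(n)[-1]) {
    d <- Dq[t, ]
    q <- c(
      q[1] * d[1] - q[2] * d[2] - q[3] * d[3] - q[4] * d[4],
      q[1] * d[2] + q[2] * d[1] + q[3] * d[4] - q[4] * d[3],
      q[1] * d[3] - q[2] * d[4] + q[3] * d[1] + q[4] * d[2],
      q[1] * d[4] + q[2] * d[3] - q[3] * d[2] + q[4] * d[1]
    )
    q <- q / sqrt(sum(q^2))
    Q[t, ] <- q
  }
  orientation_series(Q, f)
}

#' Orientation series container
#' @param Q n x 4 matrix of unit quaternions (scalar-first rows).
#' @param f Sampling rate (Hz).
#' @return `orientation_series` object.
#' @export
orientation_series <- function(Q, f) {
  stopifnot(is.matrix(Q), ncol(Q) == 4, f > 0)
  structure(Q, f = f, class = c("orientation_series", "matrix"))
}

#' Rotate sensor-frame vectors to the global frame
#'
#' @param q A single unit quaternion, or an `orientation_series` / n x 4
#'   matrix matching `v` row for row.
#' @param v A 3-vector, or an n x 3 matrix of sensor-frame vectors.
#' @return Rotated vector(s), global frame; same shape as `v`.
#' @export
rotate_to_global <- function(q, v) {
  if (is.matrix(v)) {
    Q <- if (is.matrix(q)) unclass(q) else
      matrix(as.numeric(q), nrow(v), 4, byrow = TRUE)
    return(quat_rotate_rows(Q, v))
  }
  quat_rotate(q, v)
}

#' Principal roll axis of a cycle's angular velocity
#'
#' First principal component of the global-frame angular-velocity samples over
#' one stroke cycle. Under the front-crawl roll constraint this axis should be
#' the swimming direction `[0, 1, 0]`; its deviation measures orientation
#' drift. The sign is fixed so the axis has a non-negative component along Y.
#'
#' @param omega_global m x 3 matrix of global-frame angular velocity over one
#'   cycle (rad s^-1), m >= 3.
#' @return Unit 3-vector.
#' @export
principal_roll_axis <- function(omega_global) {
  stopifnot(is.matrix(omega_global), ncol(omega_global) == 3)
  if (nrow(omega_global) < 3) stop("need at least 3 samples for a principal axis")
  C <- stats::cov(omega_global)
  if (!all(is.finite(C)) || sum(abs(C)) < .Machine$double.eps * 100) {
    stop("degenerate angular-velocity cloud: unusable cycle")
  }
  e <- eigen(C, symmetric = TRUE)
  p <- e$vectors[, 1]
  if (sum(p * .Y_GF) < 0) p <- -p
  p / sqrt(sum(p^2))
}

#' Per-cycle drift correction parameters
#'
#' From the principal roll axis of a cycle, the drift angle is its angular
#' deviation from the swimming direction and the corrective axis is the
#' horizontal-plane normal `p x [0,1,0]` (sign chosen so that rotating the
#' principal axis about it by the drift angle lands exactly on `[0,1,0]`).
#'
#' @param p_axis Unit 3-vector, principal roll axis (global frame).
#' @param n_samples Number of samples in the cycle (>= 2).
#' @param cycle_index Optional cycle label carried in the result.
#' @return A `cycle_drift_correction` list: `p_axis`, `delta_theta` (rad),
#'   `u_axis` (unit 3-vector orthogonal to Y; zero vector when no drift),
#'   `n_samples`, `cycle_index`.
#' @export
drift_correction_for_cycle <- function(p_axis, n_samples, cycle_index = NA_integer_) {
  stopifnot(length(p_axis) == 3, n_samples >= 2)
  nrm <- sqrt(sum(p_axis^2))
  stopifnot(abs(nrm - 1) < 1e-6)
  p <- p_axis / nrm
  cth <- max(-1, min(1, sum(p * .Y_GF)))
  delta_theta <- acos(cth)
  u <- pracma::cross(p, .Y_GF)
  un <- sqrt(sum(u^2))
  if (un < 1e-12) {
    u <- c(0, 0, 0)            # already aligned: correction is the identity
    delta_theta <- 0
  } else {
    u <- u / un
  }
  structure(list(p_axis = p, delta_theta = delta_theta, u_axis = u,
                 n_samples = as.integer(n_samples),
                 cycle_index = cycle_index),
            class = "cycle_drift_correction")
}

#' Corrective quaternion at a sample within a cycle
#'
#' The drift is assumed to grow linearly across the cycle, so the corrective
#' rotation ramps from the identity at the first sample to the full drift
#' angle at the last: angle `delta_theta * (t - 1) / (n - 1)` about `u_axis`.
#'
#' @param corr A `cycle_drift_correction`.
#' @param t_in_cycle 1-based sample index within the cycle.
#' @return Unit quaternion.
#' @export
corrective_quaternion <- function(corr, t_in_cycle) {
  n <- corr$n_samples
  if (n < 2) stop("cycle with a single sample cannot carry a drift ramp")
  stopifnot(t_in_cycle >= 1, t_in_cycle <= n)
  if (corr$delta_theta == 0 || all(corr$u_axis == 0)) return(quat_identity())
  ang <- corr$delta_theta * (t_in_cycle - 1) / (n - 1)
  quat_from_axis_angle(corr$u_axis, ang)
}

#' Apply per-cycle drift correction to an orientation series
#'
#' Cycles are processed in order and their corrections compound. For cycle k,
#' the global-frame angular velocity is formed from the orientation already
#' carrying the corrections of cycles 1..k-1; the principal axis of that
#' cloud measures the drift accrued *within* cycle k, which is removed by a
#' corrective quaternion ramping linearly from zero to the full cycle drift
#' angle (`q_corrected = q (x) delta_q`). Samples before the first cycle keep
#' the identity correction; samples after the last cycle hold the accumulated
#' correction constant.
#'
#' @param q_series `orientation_series` covering the recording.
#' @param cycles A `cycle_set` (see [detect_cycles()]).
#' @param gyro n x 3 sensor-frame angular velocity matrix (rad s^-1) the
#'   series was integrated from.
#' @param smooth_cycles Width (in cycles, odd) of the running mean applied to
#'   the accumulated drift trajectory before the correction is rebuilt. The
#'   roll constraint holds only on average: real pitch/yaw motion tilts a
#'   single cycle's principal axis off the forward direction by a degree or
#'   two of zero-mean noise, while true gyroscopic drift varies smoothly
#'   across cycles, so a short running mean suppresses the noise without
#'   losing the drift when it varies quickly. Constraint noise is typically
#'   correlated across neighboring cycles, so the default applies no
#'   smoothing (1); the option helps mainly against isolated weak cycles.
#' @return A list: `corrected` (`orientation_series`), `corrections` (list of
#'   `cycle_drift_correction`, one per usable cycle, each measuring that
#'   cycle's incremental drift).
#' @export
correct_orientation_series <- function(q_series, cycles, gyro,
                                       smooth_cycles = 1) {
  Q <- unclass(q_series)
  f <- attr(q_series, "f")
  n <- nrow(Q)
  stopifnot(nrow(gyro) == n)
  b <- cycles$boundaries
  if (max(b) > n + 1L) stop("cycle boundaries exceed the orientation series")
  K <- length(b) - 1L
  corrections <- list()
  acc <- c(1, 0, 0, 0)   # accumulated correction from completed cycles
  r_end <- matrix(0, K, 3)  # accumulated drift at each cycle end (rot. vector)
  usable <- logical(K)
  # pass 1: measure each cycle's incremental drift on the partially corrected
  # series (Eqs. 5-8 applied cumulatively)
  for (k in seq_len(K)) {
    i0 <- b[k]; i1 <- b[k + 1L] - 1L
    m <- i1 - i0 + 1L
    if (m >= 2L) {
      Acc <- matrix(acc, m, 4, byrow = TRUE)
      Qk <- quat_multiply_rows(Q[i0:i1, , drop = FALSE], Acc)
      omega_k <- quat_rotate_rows(Qk, gyro[i0:i1, , drop = FALSE])
      p <- tryCatch(principal_roll_axis(omega_k), error = function(e) NULL)
    } else {
      warning(sprintf("cycle %d has fewer than 2 samples; skipped", k))
      p <- NULL
    }
    if (is.null(p)) {
      if (m >= 2L) {
        warning(sprintf("cycle %d has a degenerate angular-velocity cloud; skipped", k))
      }
      r_end[k, ] <- if (k > 1) r_end[k - 1, ] else 0
      next
    }
    corr <- drift_correction_for_cycle(p, m, cycle_index = k)
    corrections[[length(corrections) + 1L]] <- corr
    usable[k] <- TRUE
    dq_full <- quat_from_axis_angle(
      if (corr$delta_theta > 0) corr$u_axis else c(1, 0, 0), corr$delta_theta)
    acc <- as.numeric(quat_multiply(quaternion(acc[1], acc[2], acc[3], acc[4]),
                                    dq_full))
    acc <- acc / sqrt(sum(acc^2))
    r_end[k, ] <- quat_to_rotvec(acc)
  }
  # pass 2: the roll constraint holds only on average, so each endpoint
  # carries zero-mean constraint noise (occasionally a spike, when a cycle's
  # angular-velocity cloud is weak) on top of the smooth true drift; a short
  # centered running *median* across cycles suppresses both
  h <- max(0L, (as.integer(smooth_cycles) - 1L) %/% 2L)
  r_hat <- r_end
  if (h > 0L && K > 1L) {
    for (k in seq_len(K)) {
      w <- min(h, k - 1L, K - k)
      r_hat[k, ] <- apply(r_end[(k - w):(k + w), , drop = FALSE], 2,
                          stats::median)
    }
  }
  # rebuild the per-sample correction: linear rotation-vector ramp from each
  # cycle's start (previous endpoint) to its end
  D <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  for (k in seq_len(K)) {
    i0 <- b[k]; i1 <- b[k + 1L] - 1L
    m <- i1 - i0 + 1L
    if (m < 2L) next
    r0 <- if (k > 1) r_hat[k - 1, ] else c(0, 0, 0)
    r1 <- r_hat[k, ]
    u <- (seq_len(m) - 1) / (m - 1)
    Rv <- outer(1 - u, r0) + outer(u, r1)
    D[i0:i1, ] <- rotvec_to_quat_rows(Rv)
  }
  last_end <- b[K + 1L] - 1L
  if (last_end < n) {
    D[(last_end + 1L):n, ] <- matrix(rotvec_to_quat_rows(rbind(r_hat[K, ])),
                                     n - last_end, 4, byrow = TRUE)
  }
  Qc <- quat_normalize_rows(quat_multiply_rows(Q, D))
  list(corrected = orientation_series(Qc, f), corrections = corrections)
}

# rotation vector (axis * angle) of a unit quaternion, angle in [0, pi]
quat_to_rotvec <- function(q) {
  if (q[1] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-15) return(c(0, 0, 0))
  2 * atan2(vn, q[1]) * q[2:4] / vn
}

# rows of rotation vectors -> rows of unit quaternions
rotvec_to_quat_rows <- function(Rv) {
  ang <- sqrt(rowSums(Rv^2))
  half <- ang / 2
  s <- ifelse(ang > 1e-15, sin(half) / pmax(ang, .Machine$double.xmin), 0.5)
  cbind(cos(half), Rv * s)
}
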