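# Velocity drift removal: GMA change-detection segmentation of forward
# acceleration, per-segment envelope-spline trend estimation, trend
# subtraction, and anchoring to the known trial mean velocity.

#' Trial metadata
#'
#' @param pool_length Pool length (m); the distance covered by the trial.
#' @param duration Trial duration (s).
#' @return A `trial_info` list with `mean_velocity = pool_length / duration`
#'   (m s^-1), the anchor for the detrended velocity.
#' @export
trial_info <- function(pool_length = 25, duration) {
  stopifnot(pool_length > 0, duration > 0)
  structure(list(pool_length = pool_length, duration = duration,
                 mean_velocity = pool_length / duration),
            class = "trial_info")
}

#' Segment set container
#' @param starts Strictly increasing segment start indices, first = 1.
#' @param n Series length; segment i covers `[starts[i], starts[i+1])`, the
#'   last segment ends at `n`.
#' @param threshold_frac Variance-change threshold used (fraction of total
#'   signal variance).
#' @return A `segment_set` with a two-column `segments` matrix (start, end;
#'   end inclusive).
#' @export
segment_set <- function(starts, n, threshold_frac = 0.20) {
  starts <- as.integer(starts)
  stopifnot(length(starts) >= 1, starts[1] == 1L, all(diff(starts) > 0),
            max(starts) <= n)
  ends <- c(starts[-1] - 1L, as.integer(n))
  structure(list(segments = cbind(start = starts, end = ends),
                 n_segments = length(starts), n = as.integer(n),
                 threshold_frac = threshold_frac),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segment(s) over %d samples (threshold %.0f%% of variance)\n",
              x$n_segments, x$n, 100 * x$threshold_frac))
  invisible(x)
}

#' Geometric-moving-average change detection
#'
#' Tracks an exponentially weighted (geometric moving average) estimate of the
#' forward-acceleration mean and variance,
#' `m_t = lambda m_{t-1} + (1-lambda) a_t` and
#' `s2_t = lambda s2_{t-1} + (1-lambda) (a_t - m_t)^2`.
#' A new segment opens when the running variance departs from the reference
#' variance frozen at the last change point by more than `threshold_frac`
#' times the whole-series variance of `a`. Swimming-regime changes show up as
#' changes of acceleration amplitude, which is what this detects.
#'
#' @param a_forward Forward acceleration series (m s^-2).
#' @param threshold_frac Detection threshold as a fraction of `var(a_forward)`
#'   (default 0.20).
#' @param lambda Forgetting factor of the recursions (default 0.999; at 500 Hz
#'   an effective memory of about 2 s, one to two stroke cycles: long enough
#'   that intra-cycle acceleration oscillation does not leak into the variance
#'   estimate, short enough to flag a regime change within a couple of cycles).
#' @param min_len Minimum segment length in samples (e.g. one stroke cycle);
#'   shorter segments are merged into their neighbor. 0 disables merging.
#' @return A [segment_set()].
#' @export
gma_segment <- function(a_forward, threshold_frac = 0.20, lambda = 0.999,
                        min_len = 0L) {
  a <- as.numeric(a_forward)
  n <- length(a)
  stopifnot(threshold_frac > 0, lambda > 0, lambda < 1)
  if (n < 2 / (1 - lambda)) {
    stop("series shorter than twice the GMA memory; cannot segment")
  }
  vtot <- stats::var(a)
  thr <- threshold_frac * vtot
  warmup <- ceiling(1 / (1 - lambda))
  # seed the recursion from the first warm-up window so the running variance
  # starts converged (an exponential ramp from zero would itself look like a
  # change); after each detected change the tracker re-seeds the same way
  seed_window <- function(from) {
    to <- min(n, from + warmup - 1L)
    list(m = mean(a[from:to]), s2 = stats::var(a[from:to]))
  }
  st <- seed_window(1L)
  m <- st$m; s2 <- st$s2; s2_ref <- s2
  starts <- 1L
  last_change <- 1L
  t <- 2L
  while (t <= n) {
    m <- lambda * m + (1 - lambda) * a[t]
    s2 <- lambda * s2 + (1 - lambda) * (a[t] - m)^2
    if (t > last_change + warmup && abs(s2 - s2_ref) > thr) {
      starts <- c(starts, t)
      last_change <- t
      st <- seed_window(t)
      m <- st$m; s2 <- st$s2; s2_ref <- s2
      t <- min(n, t + warmup - 1L)   # the seeding window is consumed
    }
    t <- t + 1L
  }
  # post-hoc validation: a segment exists because the acceleration variance
  # left the previous regime's interval, so adjacent segments whose sample
  # variances differ by less than the detection threshold are one regime —
  # merging them removes detector false alarms
  while (length(starts) > 1L) {
    ends <- c(starts[-1] - 1L, n)
    vs <- vapply(seq_along(starts),
                 function(i) stats::var(a[starts[i]:ends[i]]), numeric(1))
    dv <- abs(diff(vs))
    if (all(dv > thr)) break
    i <- which.min(dv)
    starts <- starts[-(i + 1L)]
  }
  if (min_len > 0L && length(starts) > 1L) {
    lens <- diff(c(starts, n + 1L))
    while (length(starts) > 1L && any(lens < min_len)) {
      i <- which.min(lens)             # merge the shortest into its left
      starts <- if (i == 1L) starts[-2L] else starts[-i]  # neighbor (or right
      lens <- diff(c(starts, n + 1L))  # for the first segment)
    }
  }
  segment_set(starts, n, threshold_frac)
}

#' Per-segment peak-envelope velocity trend
#'
#' Within each segment the average trend of the velocity peaks is taken as
#' quasi-constant (steady swimming regime). One maximum and one minimum peak
#' of `v` are extracted per stroke cycle; shape-preserving piecewise cubics
#' (Fritsch-Carlson, non-overshooting) are fitted through the maxima and the
#' minima; the drift trend is the pointwise average of the two envelope
#' curves, held constant beyond the outermost knots of each segment.
#'
#' @param v Raw (drifting) velocity series (m s^-1).
#' @param segments A [segment_set()] from [gma_segment()].
#' @param cycles A [cycle_set()].
#' @return A `trend_model` list: `trend` (per-sample, m s^-1), `upper_knots`,
#'   `lower_knots` (matrices of sample index and velocity), `per_segment`
#'   bookkeeping.
#' @export
fit_trend <- function(v, segments, cycles) {
  v <- as.numeric(v)
  n <- length(v)
  stopifnot(segments$n == n)
  trend <- numeric(n)
  up_all <- low_all <- NULL
  seginfo <- vector("list", segments$n_segments)
  for (s in seq_len(segments$n_segments)) {
    s0 <- segments$segments[s, "start"]; s1 <- segments$segments[s, "end"]
    # only cycles fully contained in the segment contribute peaks: fragments
    # straddling a boundary mix regimes and would bend the envelope
    ks <- which(cycles$boundaries[-length(cycles$boundaries)] >= s0 &
                cycles$boundaries[-1] - 1L <= s1)
    ux <- uy <- lx <- ly <- numeric(0)
    for (k in ks) {
      idx <- cycle_range(cycles, k)
      if (length(idx) < 2) next
      ux <- c(ux, idx[which.max(v[idx])]); uy <- c(uy, max(v[idx]))
      lx <- c(lx, idx[which.min(v[idx])]); ly <- c(ly, min(v[idx]))
    }
    xs <- s0:s1
    if (length(ux) < 2 || length(lx) < 2) {
      message(sprintf(
        "trend segment %d has fewer than 2 cycles; using its mean velocity", s))
      trend[xs] <- mean(v[xs])
      seginfo[[s]] <- list(constant = TRUE)
      next
    }
    # shape-preserving interpolant through the peaks; query points are
    # clamped to the knot range so the envelope extends as a constant
    # (pchip needs >= 3 knots; 2 knots degrade to linear, also
    # non-overshooting)
    envel <- function(kx, ky) {
      xq <- pmin(pmax(xs, min(kx)), max(kx))
      if (length(kx) >= 3) pracma::pchip(kx, ky, xq)
      else stats::approx(kx, ky, xout = xq)$y
    }
    upper <- envel(ux, uy)
    lower <- envel(lx, ly)
    trend[xs] <- (upper + lower) / 2
    up_all <- rbind(up_all, cbind(index = ux, v = uy))
    low_all <- rbind(low_all, cbind(index = lx, v = ly))
    seginfo[[s]] <- list(constant = FALSE, n_cycles = length(ks),
                         first_knot = (min(ux) + min(lx)) / 2,
                         last_knot = (max(ux) + max(lx)) / 2)
  }
  structure(list(trend = trend, upper_knots = up_all, lower_knots = low_all,
                 per_segment = seginfo,
                 segments = segments$segments),
            class = "trend_model")
}

# Drift estimate from a trend model: the within-segment variation of the
# envelope midline, stitched so the drift curve is continuous across segment
# boundaries. Integration drift is continuous in time; genuine
# swimming-regime level steps between segments are not drift and are kept.
trend_drift <- function(trend) {
  if (!inherits(trend, "trend_model")) {
    tr <- as.numeric(trend)
    return(tr - tr[1])
  }
  tr <- trend$trend
  seg <- trend$segments
  d <- numeric(length(tr))
  offset <- tr[1]
  for (s in seq_len(nrow(seg))) {
    i0 <- seg[s, "start"]; i1 <- seg[s, "end"]
    if (s > 1) offset <- offset + tr[i0] - tr[seg[s - 1, "end"]]
    d[i0:i1] <- tr[i0:i1] - offset
  }
  d
}

#' Subtract the drift trend and anchor to the trial mean velocity
#'
#' The drift estimate — the within-segment variation of the envelope-midline
#' trend, stitched continuously across segment boundaries — is subtracted
#' from the raw velocity, then a constant offset is added so the whole-trial
#' mean equals the known mean velocity `pool_length / duration` (drift from
#' integration is additive in velocity, hence an additive anchor).
#'
#' @param v Raw velocity series (m s^-1).
#' @param trend A `trend_model` from [fit_trend()] (or a numeric series).
#' @param trial A [trial_info()].
#' @param f Sampling rate (Hz).
#' @param cycles Optional [cycle_set()] to attach cycle means.
#' @return A [velocity_profile()].
#' @export
detrend_velocity <- function(v, trend, trial, f, cycles = NULL) {
  d <- trend_drift(trend)
  stopifnot(length(d) == length(v))
  out <- as.numeric(v) - d
  out <- out + (trial$mean_velocity - mean(out))
  velocity_profile(out, f, cycles)
}
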