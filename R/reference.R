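# Tethered-speedometer reference: parallax correction of cord-displacement
# data and resampling utilities for IMU-vs-reference comparison.

#' Reference recording container
#'
#' A poolside tethered speedometer pays out a cord from a pulley mounted above
#' water level; it records the cord length over time. Because the pulley sits
#' above the swimmer, the cord is not parallel to the swimming direction
#' (parallax).
#'
#' @param cord_length Cord length from pulley to swimmer per sample (m).
#' @param f_ref Sampling rate (Hz), 100 by default.
#' @param pulley_height Pulley height above still water level (m), 0.72 by
#'   default.
#' @param t Optional time stamps (s).
#' @return A `reference_recording` list.
#' @export
reference_recording <- function(cord_length, f_ref = 100, pulley_height = 0.72,
                                t = NULL) {
  cord_length <- as.numeric(cord_length)
  stopifnot(f_ref > 0, pulley_height >= 0)
  if (any(cord_length < pulley_height - 1e-9)) {
    stop("cord length shorter than the pulley height: corrupt reference data")
  }
  n <- length(cord_length)
  if (is.null(t)) t <- (seq_len(n) - 1) / f_ref
  structure(list(t = t, cord_length = cord_length, f_ref = f_ref,
                 pulley_height = pulley_height, n = n),
            class = "reference_recording")
}

#' @export
print.reference_recording <- function(x, ...) {
  cat(sprintf(
    "reference_recording: %d samples at %g Hz, pulley %.2f m above water\n",
    x$n, x$f_ref, x$pulley_height))
  invisible(x)
}

#' Parallax-corrected forward velocity of the tethered reference
#'
#' With the pulley a height `h` above the water, a cord length `L` places the
#' swimmer a horizontal distance `x = sqrt(L^2 - h^2)` from the pulley base.
#' The forward velocity is the centered finite difference of `x` (one-sided
#' at the series endpoints), which has zero phase lag.
#'
#' @param ref A [reference_recording()].
#' @return Forward velocity series (m s^-1) at `ref$f_ref`.
#' @export
parallax_correct <- function(ref) {
  L <- ref$cord_length
  h <- ref$pulley_height
  n <- ref$n
  f <- ref$f_ref
  x <- sqrt(pmax(L^2 - h^2, 0))
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * f
  v[n] <- (x[n] - x[n - 1]) * f
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * f / 2
  sing <- which(abs(L - h) < 1e-12)
  sing <- sing[sing > 1 & sing < n]
  if (length(sing)) {
    # swimmer directly beneath the pulley: x is not differentiable in L there;
    # fall back to a one-sided difference
    warning(sprintf("%d sample(s) at the parallax singularity (L = h)", length(sing)))
    v[sing] <- (x[sing + 1L] - x[sing]) * f
  }
  v
}

#' Resample a velocity series to a lower rate
#'
#' Zero-phase anti-alias low-pass (0.45 of the target Nyquist-matched cutoff)
#' followed by interpolation onto the target grid. Comparisons against the
#' 100 Hz reference require the 500 Hz IMU estimate to be brought to a common
#' rate first.
#'
#' @param v Velocity series at `f_src`.
#' @param f_src Source sampling rate (Hz).
#' @param f_dst Target sampling rate (Hz), `<= f_src`.
#' @return Velocity series at `f_dst`, length `floor(length(v) * f_dst / f_src)`.
#' @export
resample_to <- function(v, f_src, f_dst) {
  stopifnot(f_src > 0, f_dst > 0, f_src >= f_dst)
  v <- as.numeric(v)
  if (f_src == f_dst) return(v)
  vf <- lowpass_zerophase(v, f_src, 0.45 * f_dst, order = 4)
  n_out <- floor(length(v) * f_dst / f_src)
  t_src <- (seq_along(v) - 1) / f_src
  t_dst <- (seq_len(n_out) - 1) / f_dst
  stats::approx(t_src, vf, xout = t_dst, rule = 2)$y
}
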