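# Internal helpers.

# Zero-phase Butterworth low-pass with edge-reflection padding.
# signal::filtfilt alone leaves large transients at the series ends, so the
# series is extended by reflecting it about each endpoint before filtering and
# trimmed afterwards (the scheme MATLAB's filtfilt uses).
lowpass_zerophase <- function(x, f, cutoff_hz, order = 2) {
  n <- length(x)
  wc <- cutoff_hz / (f / 2)
  if (wc >= 1) return(x)
  bf <- signal::butter(order, wc)
  npad <- min(n - 1L, max(3L * 10L * order, ceiling(3 * f / cutoff_hz)))
  head_pad <- 2 * x[1] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(npad + 1L):(npad + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
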