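# Agreement and variability statistics: nPVI, IVV, Bland-Altman limits of
# agreement with heteroscedasticity check, instantaneous error measures, and
# Spearman rank correlation.
#
# Internal computation is in m/s; reporting of agreement statistics is in
# cm/s, the customary unit for swimming-velocity errors.

#' Normalized pairwise variability index (nPVI)
#'
#' Percentage disagreement between two paired cycle-mean sequences: 100 times
#' the mean over pairs of `|ref - est| / ((ref + est) / 2)`.
#'
#' @param ref_means,est_means Paired cycle-mean velocities (m s^-1), equal
#'   length, strictly positive.
#' @return nPVI in percent.
#' @export
npvi <- function(ref_means, est_means) {
  stopifnot(length(ref_means) == length(est_means), length(ref_means) >= 1)
  if (any(ref_means <= 0) || any(est_means <= 0)) {
    stop("nPVI requires strictly positive velocities")
  }
  100 * mean(abs(ref_means - est_means) / ((ref_means + est_means) / 2))
}

#' Intra-cyclic velocity variation (IVV)
#'
#' Normalized within-cycle velocity fluctuation: the cycle-frequency-weighted
#' RMS of the deviations of instantaneous velocity from its cycle mean,
#' divided by the equally weighted mean velocity, in percent,
#' \deqn{IVV = 100 \frac{\sqrt{\sum_k \sum_{t \in C_k} (V_t - \bar V_{C_k})^2 f_{C_k} / n}}
#'                  {\sum_k \sum_{t \in C_k} V_t f_{C_k} / n}}
#' with `n` the total number of trial samples. Lower in elite swimmers.
#'
#' @param v Velocity series (m s^-1), positive on average.
#' @param cycles A [cycle_set()].
#' @return An `ivv_result` list: `ivv` (percent) and `per_cycle_contributions`
#'   (each cycle's weighted squared-deviation sum).
#' @export
ivv <- function(v, cycles) {
  v <- as.numeric(v)
  if (max(cycles$boundaries) - 1L > length(v)) {
    stop("cycle boundaries exceed the velocity series")
  }
  if (cycles$n_cycles < 1) stop("need at least one full cycle")
  n <- length(v)
  num_k <- den_k <- numeric(cycles$n_cycles)
  for (k in seq_len(cycles$n_cycles)) {
    idx <- cycle_range(cycles, k)
    vk <- v[idx]
    fk <- cycles$f_cycle[k]
    num_k[k] <- sum((vk - mean(vk))^2) * fk / n
    den_k[k] <- sum(vk) * fk / n
  }
  den <- sum(den_k)
  if (den <= 0) stop("IVV undefined: non-positive mean velocity over the cycles")
  structure(list(ivv = 100 * sqrt(sum(num_k)) / den,
                 per_cycle_contributions = num_k),
            class = "ivv_result")
}

#' Bland-Altman agreement of paired cycle means
#'
#' Differences are taken as `est - ref`. Bias is their mean (accuracy),
#' precision their sample standard deviation, and the 95% limits of agreement
#' are bias +/- 1.96 SD. Heteroscedasticity is screened as the Pearson
#' correlation between pair means and pair differences.
#'
#' @param ref_means,est_means Paired sequences (m s^-1), equal length >= 2.
#' @return List with `bias`, `precision`, `loa_low`, `loa_high` (all cm s^-1),
#'   `hetero_corr`, `differences` and `means` (m s^-1).
#' @export
bland_altman <- function(ref_means, est_means) {
  stopifnot(length(ref_means) == length(est_means), length(ref_means) >= 2)
  d <- est_means - ref_means
  m <- (est_means + ref_means) / 2
  bias <- mean(d)
  precision <- stats::sd(d)
  hetero <- if (stats::sd(m) == 0 || precision == 0) 0 else stats::cor(m, d)
  list(bias = 100 * bias,
       precision = 100 * precision,
       loa_low = 100 * (bias - 1.96 * precision),
       loa_high = 100 * (bias + 1.96 * precision),
       hetero_corr = hetero,
       differences = d, means = m)
}

#' Instantaneous velocity error measures
#'
#' @param v_est,v_ref Time-aligned velocity series at a common rate (m s^-1),
#'   equal length.
#' @return List with `rms` and `max_abs` (cm s^-1) and `max_relative`
#'   (percent, the maximum absolute difference relative to the reference
#'   velocity at the sample where it occurs; if that reference sample is zero
#'   the trial-mean reference velocity is used instead, with a warning).
#' @export
instantaneous_errors <- function(v_est, v_ref) {
  stopifnot(length(v_est) == length(v_ref), length(v_est) >= 1)
  d <- v_est - v_ref
  rms <- sqrt(mean(d^2))
  i <- which.max(abs(d))
  max_abs <- abs(d[i])
  denom <- v_ref[i]
  if (abs(denom) < .Machine$double.eps) {
    warning("zero reference velocity at the maximum error; using the trial mean")
    denom <- mean(v_ref)
  }
  list(rms = 100 * rms, max_abs = 100 * max_abs,
       max_relative = 100 * max_abs / abs(denom))
}

#' Spearman rank correlation of paired cycle means
#'
#' @param ref,est Paired sequences, equal length >= 3.
#' @return Rank correlation (average ranks for ties).
#' @export
spearman <- function(ref, est) {
  stopifnot(length(ref) == length(est), length(ref) >= 3)
  if (stats::sd(ref) == 0 || stats::sd(est) == 0) {
    stop("Spearman correlation undefined for a constant sequence")
  }
  stats::cor(ref, est, method = "spearman")
}

#' Assemble a full agreement report
#'
#' Bundles every evaluation statistic for an estimate/reference pair: cycle
#' mean agreement (bias, precision, limits of agreement, Spearman rho, nPVI,
#' heteroscedasticity screen) and instantaneous error measures.
#'
#' @param ref_means,est_means Paired cycle-mean velocities (m s^-1).
#' @param v_est,v_ref Time-aligned instantaneous velocity at a common rate
#'   (m s^-1); optional.
#' @param extra Named list merged into the report (e.g. IVV values, lag).
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(ref_means, est_means, v_est = NULL, v_ref = NULL,
                             extra = list()) {
  ba <- bland_altman(ref_means, est_means)
  rep <- list(
    n_cycles = length(ref_means),
    bias = ba$bias, precision = ba$precision,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    hetero_corr = ba$hetero_corr,
    spearman_rho = if (length(ref_means) >= 3) spearman(ref_means, est_means) else NA_real_,
    npvi = npvi(ref_means, est_means)
  )
  if (!is.null(v_est) && !is.null(v_ref)) {
    ie <- instantaneous_errors(v_est, v_ref)
    rep$rms_instant <- ie$rms
    rep$max_instant <- ie$max_abs
    rep$max_relative <- ie$max_relative
  }
  rep <- c(rep, extra)
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (IMU estimate vs reference)\n")
  cat(sprintf("  cycles compared     : %d\n", x$n_cycles))
  cat(sprintf("  cycle-mean bias     : %6.2f cm/s (precision %.2f cm/s)\n",
              x$bias, x$precision))
  cat(sprintf("  95%% limits of agr.  : [%.2f, %.2f] cm/s\n", x$loa_low, x$loa_high))
  cat(sprintf("  heteroscedasticity  : r = %.3f\n", x$hetero_corr))
  if (!is.na(x$spearman_rho))
    cat(sprintf("  Spearman rho        : %.3f\n", x$spearman_rho))
  cat(sprintf("  nPVI                : %.2f %%\n", x$npvi))
  if (!is.null(x$rms_instant)) {
    cat(sprintf("  instantaneous RMS   : %.2f cm/s\n", x$rms_instant))
    cat(sprintf("  instantaneous max   : %.2f cm/s (relative %.2f %%)\n",
                x$max_instant, x$max_relative))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param ba Output of [bland_altman()] (or an [agreement_report()] built
#'   from the same pairs, in which case pass the pairs again).
#' @param xlab,ylab,main Plot labels.
#' @return Invisibly, the limits drawn.
#' @export
plot_bland_altman <- function(ba, xlab = "mean of pair (m/s)",
                              ylab = "difference est - ref (m/s)",
                              main = "Bland-Altman agreement") {
  graphics::plot(ba$means, ba$differences, pch = 16, cex = 0.7,
                 xlab = xlab, ylab = ylab, main = main)
  lims <- c(ba$loa_low, ba$bias, ba$loa_high) / 100
  graphics::abline(h = lims, lty = c(3, 2, 3))
  invisible(lims)
}
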