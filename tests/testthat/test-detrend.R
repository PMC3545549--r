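# GMA change detection, envelope-spline trend, drift removal and anchoring.

test_that("stationary noise yields one segment; huge thresholds always do", {
  set.seed(51)
  a <- stats::rnorm(10000)
  seg <- gma_segment(a)
  expect_equal(seg$n_segments, 1L)
  expect_equal(seg$segments[1, ], c(start = 1L, end = 10000L))

  set.seed(52)
  a2 <- c(stats::rnorm(5000, sd = 1), stats::rnorm(5000, sd = sqrt(2)))
  seg2 <- gma_segment(a2, threshold_frac = 1.01)  # above total variance
  expect_equal(seg2$n_segments, 1L)
})

test_that("a variance step is localized within 250 samples", {
  set.seed(53)
  a <- c(stats::rnorm(5000, sd = 1), stats::rnorm(5000, sd = 2))
  seg <- gma_segment(a, threshold_frac = 0.20)
  expect_gte(seg$n_segments, 2L)
  expect_lte(abs(seg$segments[2, "start"] - 5000L), 250L)
})

test_that("lowering the threshold never reduces the segment count", {
  for (s in 1:4) {
    set.seed(60 + s)
    a <- c(stats::rnorm(4000, sd = 1), stats::rnorm(3000, sd = 2),
           stats::rnorm(3000, sd = 1.3))
    n_seg <- vapply(c(0.25, 0.20, 0.15),
                    function(th) gma_segment(a, threshold_frac = th)$n_segments,
                    integer(1))
    expect_true(all(diff(n_seg) >= 0))
  }
})

test_that("segments shorter than min_len are merged away", {
  set.seed(54)
  a <- c(stats::rnorm(4000, sd = 1), stats::rnorm(300, sd = 4),
         stats::rnorm(4000, sd = 1))
  seg <- gma_segment(a, min_len = 800)
  expect_true(all(diff(c(seg$segments[, "start"], length(a) + 1L)) >= 800))
})

test_that("trend of a drift-free oscillation is its constant midline", {
  f <- 500
  t <- seq(0, 20, by = 1 / f)
  v <- 1.4 + 0.2 * sin(2 * pi * 0.75 * t)
  n <- length(v)
  cyc <- uniform_cycles(14, round(f / 0.75), f)
  seg <- segment_set(1L, n)
  tr <- fit_trend(v, seg, cyc)
  expect_lt(max(abs(tr$trend - 1.4)), 0.01)
  # upper envelope sits on the peaks, lower on the troughs
  expect_true(all(tr$upper_knots[, "v"] > tr$lower_knots[, "v"]))
})

test_that("trend recovers an injected linear ramp", {
  f <- 500
  t <- seq(0, 20, by = 1 / f)
  v <- 1.4 + 0.2 * sin(2 * pi * 0.75 * t) + 0.05 * t
  cyc <- uniform_cycles(14, round(f / 0.75), f)
  tr <- fit_trend(v, segment_set(1L, length(v)), cyc)
  interior <- seq(round(f / 0.75) + 1, 13 * round(f / 0.75))
  expect_lt(max(abs(tr$trend[interior] - (1.4 + 0.05 * t[interior]))), 0.02)
})

test_that("the fitted trend never overshoots its envelope knots", {
  set.seed(55)
  f <- 100
  for (i in 1:5) {
    n <- 3000
    cyc <- uniform_cycles(9, 300, f)
    # random smooth level + oscillation + noise: arbitrary peak layout
    lv <- cumsum(stats::rnorm(n, sd = 0.01))
    v <- lv + sin(2 * pi * (1:n) / 300 * 2) * stats::runif(1, 0.1, 0.5)
    tr <- fit_trend(v, segment_set(1L, n), cyc)
    expect_lte(max(tr$trend), max(tr$upper_knots[, "v"]) + 1e-9)
    expect_gte(min(tr$trend), min(tr$lower_knots[, "v"]) - 1e-9)
  }
})

test_that("a short segment falls back to its mean with a message", {
  f <- 100
  v <- 1 + 0.1 * sin(2 * pi * (0:999) / 200)
  cyc <- uniform_cycles(4, 200, f)
  seg <- segment_set(c(1L, 901L), 1000L)   # second segment has no full cycle
  expect_message(tr <- fit_trend(v, seg, cyc), "fewer than 2 cycles")
  expect_equal(tr$trend[950], mean(v[901:1000]), tolerance = 1e-12)
})

test_that("detrending is a no-op when there is no trend and the mean matches", {
  f <- 100
  v <- 1.3 + 0.1 * sin(2 * pi * (0:999) / 100)
  trial <- trial_info(pool_length = mean(v) * 9.99 / 0.999, duration = 9.99 / 0.999)
  out <- detrend_velocity(v, rep(0, 1000), trial, f)
  expect_equal(out$v, v, tolerance = 1e-9)
})

test_that("mean anchoring holds to within 1e-9", {
  sim <- simulate_swim(default_scenarios(seed = 56)$recreational_t2)
  est <- estimate_quiet(sim)
  expect_lt(abs(mean(est$profile$v) - sim$trial$mean_velocity), 1e-9)
})

test_that("injected accelerometer bias drift is removed", {
  cfg <- quiet_config(default_scenarios(seed = 57)$elite_t3,
                      accel_bias = c(0, 0.05, 0))
  sim <- simulate_swim(cfg)
  est <- estimate_quiet(sim)
  v <- est$profile$v; vt <- sim$truth$velocity
  expect_lt(sqrt(mean((v - vt)^2)), 0.06)

  # cycle-wise peak-to-peak amplitude is preserved within 10% for >=90% of cycles
  cyc <- est$cycles
  ok <- vapply(seq_len(cyc$n_cycles), function(k) {
    idx <- cyc$boundaries[k]:(cyc$boundaries[k + 1] - 1)
    pp_e <- diff(range(v[idx])); pp_t <- diff(range(vt[idx]))
    abs(pp_e - pp_t) / pp_t < 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.90)

  # detrending does not cancel the intra-cyclic velocity variation
  expect_lt(abs(ivv(v, cyc)$ivv - ivv(vt, cyc)$ivv) / ivv(vt, cyc)$ivv, 0.10)
})

test_that("detrending its own output changes little (idempotence)", {
  cfg <- quiet_config(default_scenarios(seed = 58)$elite_t3,
                      accel_bias = c(0, 0.05, 0))
  sim <- simulate_swim(cfg)
  est <- estimate_quiet(sim)
  first_corr <- sqrt(mean((est$raw_velocity -
                            (est$profile$v - mean(est$profile$v) +
                             mean(est$raw_velocity)))^2))
  tr2 <- suppressMessages(fit_trend(est$profile$v, est$segments, est$cycles))
  out2 <- detrend_velocity(est$profile$v, tr2, sim$trial, est$profile$f)
  second_change <- sqrt(mean((out2$v - est$profile$v)^2))
  expect_lt(second_change, 0.05 * first_corr)
})
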