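# Agreement statistics: nPVI, IVV, Bland-Altman, instantaneous errors,
# Spearman. Derived values come from direct-summation oracles.

test_that("nPVI matches hand-evaluated pairs and is zero for identical input", {
  expect_equal(npvi(c(1.2, 1.4), c(1.2, 1.4)), 0)
  expect_equal(npvi(1.0, 1.1), 100 * (0.1 / 1.05), tolerance = 1e-9)
  expect_equal(npvi(c(1.0, 1.2), c(1.1, 1.2)), 100 * (0.1 / 1.05) / 2,
               tolerance = 1e-9)
  expect_error(npvi(c(1, 2), c(1, -2)), "positive")
  expect_error(npvi(c(1, 2), c(1, 2, 3)))
})

test_that("nPVI is symmetric and scale invariant", {
  set.seed(81)
  for (i in 1:10) {
    a <- stats::runif(8, 0.9, 2); b <- stats::runif(8, 0.9, 2)
    expect_equal(npvi(a, b), npvi(b, a), tolerance = 1e-12)
    expect_equal(npvi(3.7 * a, 3.7 * b), npvi(a, b), tolerance = 1e-12)
  }
})

test_that("IVV is zero for constant velocity and matches the sinusoid limit", {
  f <- 500
  cyc <- uniform_cycles(10, f, f)           # ten 1 s cycles at 1 Hz
  expect_equal(ivv(rep(1.4, 10 * f + 1), cyc)$ivv, 0)

  t <- (0:(10 * f)) / f
  v <- 1 + 0.2 * sin(2 * pi * t)
  r <- ivv(v, cyc)
  expect_equal(r$ivv, 100 * 0.2 / sqrt(2), tolerance = 0.5 / 14.14)
})

test_that("IVV equals the brute-force double loop on random data", {
  set.seed(82)
  f <- 50
  lens <- c(40, 55, 47, 60)
  b <- cumsum(c(1, lens))
  cyc <- cycle_set(b, f)
  v <- 1.5 + stats::rnorm(max(b), sd = 0.2)
  n <- length(v)
  num <- den <- 0
  for (k in seq_along(lens)) {
    fk <- f / lens[k]
    vk <- v[b[k]:(b[k + 1] - 1)]
    num <- num + sum((vk - mean(vk))^2) * fk / n
    den <- den + sum(vk) * fk / n
  }
  expect_equal(ivv(v, cyc)$ivv, 100 * sqrt(num) / den, tolerance = 1e-9)
})

test_that("Bland-Altman bias, precision and limits follow the n-1 SD", {
  r <- bland_altman(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r$bias, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(0, 0))

  ref <- c(1.0, 1.1, 1.2)
  est <- ref + c(-0.01, 0, 0.01)           # differences -1, 0, 1 cm/s
  r <- bland_altman(ref, est)
  expect_equal(r$bias, 0, tolerance = 1e-9)
  expect_equal(r$precision, 1, tolerance = 1e-9)
  expect_equal(r$loa_high, 1.96, tolerance = 1e-9)
  expect_equal(r$loa_high - r$loa_low, 2 * 1.96 * r$precision,
               tolerance = 1e-9)

  # differences proportional to means flag heteroscedasticity
  m <- seq(1, 2, length.out = 20)
  rh <- bland_altman(m - 0.05 * m, m + 0.05 * m)
  expect_gt(abs(rh$hetero_corr), 0.99)

  set.seed(83)
  a <- stats::rnorm(30, 1.4, 0.2); b <- a + stats::rnorm(30, 0.01, 0.05)
  r2 <- bland_altman(a, b)
  d <- b - a
  expect_equal(r2$precision / 100,
               sqrt(sum((d - mean(d))^2) / (length(d) - 1)), tolerance = 1e-12)
})

test_that("instantaneous errors match their direct formulas", {
  r0 <- instantaneous_errors(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(r0[c("rms", "max_abs", "max_relative")]),
               c(rms = 0, max_abs = 0, max_relative = 0))

  r1 <- instantaneous_errors(rep(1.5, 50), rep(1.4, 50))
  expect_equal(r1$rms, 10, tolerance = 1e-9)
  expect_equal(r1$max_abs, 10, tolerance = 1e-9)

  set.seed(84)
  a <- stats::runif(100, 1, 2); b <- a + stats::rnorm(100, sd = 0.1)
  r2 <- instantaneous_errors(b, a)
  d <- b - a
  i <- which.max(abs(d))
  expect_equal(r2$rms / 100, sqrt(sum(d^2) / 100), tolerance = 1e-12)
  expect_equal(r2$max_abs / 100, abs(d[i]), tolerance = 1e-12)
  expect_equal(r2$max_relative, 100 * abs(d[i]) / a[i], tolerance = 1e-12)
})

test_that("Spearman correlation tracks monotone relations and rank oracles", {
  x <- c(1.1, 1.3, 1.2, 1.8, 1.5)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, -x^3), -1)
  set.seed(85)
  a <- stats::rnorm(40); b <- a + stats::rnorm(40)
  expect_equal(spearman(a, b),
               stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("agreement reports assemble all statistics coherently", {
  set.seed(86)
  ref <- stats::runif(20, 1.2, 1.8)
  est <- ref + stats::rnorm(20, 0.005, 0.03)
  rep <- agreement_report(ref, est, v_est = est, v_ref = ref)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$loa_high - rep$loa_low, 2 * 1.96 * rep$precision,
               tolerance = 1e-9)
  expect_true(abs(rep$spearman_rho) <= 1 && abs(rep$hetero_corr) <= 1)
  expect_output(print(rep), "cycle-mean bias")
})
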