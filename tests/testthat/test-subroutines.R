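test_that("autocorrelation follows the raw-sum definition", {
  # constant signal: c_n = (T - n) * f^2, so r_n = (T - n) / T
  f <- rep(3, 10)
  ac <- autocorrelation(f, dt = 1, max_lag = 9)
  expect_equal(ac$r[1], 1)
  expect_equal(ac$r[ac$lag == 5], 0.5)
  expect_equal(ac$r, (10 - 0:9) / 10)
  # scale invariance
  x <- sin(2 * pi * seq(0, 5, 0.01)) + rnorm(501, 0, 0.1)
  r1 <- autocorrelation(x, 0.01, 2)$r
  r2 <- autocorrelation(-3.7 * x, 0.01, 2)$r
  expect_equal(r1, r2)
  expect_error(autocorrelation(rep(0, 100), 0.01, 0.5), "zero")
  expect_error(autocorrelation(x, 0.01, 6), "shorter")
})

test_that("dominant periods find the fundamental of a sinusoid", {
  P <- 0.5
  dt <- P / 100
  x <- sin(2 * pi * seq(0, 10 * P, dt) / P)
  peaks <- dominant_periods(autocorrelation(x, dt, 3 * P))
  expect_gt(nrow(peaks), 0)
  expect_equal(peaks$lag[1], P, tolerance = dt / P + 1e-9)
  # harmonically related peaks appear near multiples of P
  expect_true(any(abs(peaks$lag - 2 * P) <= dt + 1e-9))
})

test_that("dominant periods are empty for monotone-decaying autocorrelation", {
  x <- exp(-seq(0, 5, 0.01))
  expect_equal(nrow(dominant_periods(autocorrelation(x, 0.01, 2))), 0)
})

test_that("white-noise autocorrelation has no strong peaks", {
  set.seed(5)
  x <- rnorm(1e4)
  peaks <- dominant_periods(autocorrelation(x, 1, 500))
  expect_lt(max(peaks$r), 0.3)
})

test_that("local extrema segment at zero crossings with earliest-time ties", {
  ex <- local_extrema(c(2, 5, 5, 1), t = c(0, 1, 2, 3))
  expect_equal(nrow(ex$maxima), 1)
  expect_equal(ex$maxima$value, 5)
  expect_equal(ex$maxima$time, 1) # first of the tied samples
  expect_equal(nrow(ex$minima), 0)

  t <- seq(0, 2, by = 0.001)
  ex <- local_extrema(sin(2 * pi * t), t)
  expect_equal(nrow(ex$maxima), 2)
  expect_equal(nrow(ex$minima), 2)
  expect_equal(ex$maxima$value, c(1, 1), tolerance = 1e-4)
  expect_equal(ex$minima$value, c(-1, -1), tolerance = 1e-4)

  ex <- local_extrema(c(-3, -1, -7), t = 0:2)
  expect_equal(nrow(ex$maxima), 0)
  expect_equal(ex$minima$value, -7)
})

test_that("every sample belongs to exactly one sign-pure segment", {
  set.seed(9)
  for (i in 1:20) {
    f <- rnorm(200)
    ex <- local_extrema(f)
    runs <- rle(ifelse(f >= 0, 1L, -1L))
    expect_equal(nrow(ex$maxima) + nrow(ex$minima), length(runs$lengths))
    expect_true(all(ex$maxima$value >= 0))
    expect_true(all(ex$minima$value < 0))
  }
})

test_that("extrema summary reproduces brute-force means and global extrema", {
  ex <- list(maxima = data.frame(value = c(2, 4), time = c(0, 1)),
             minima = data.frame(value = c(-1, -5), time = c(2, 3)))
  s <- extrema_summary(ex)
  expect_equal(s$avg_local_max, 3)
  expect_equal(s$global_max, 4)
  expect_equal(s$avg_local_min, -3)
  expect_equal(s$global_min, -5)
  one <- list(maxima = data.frame(value = 7, time = 0),
              minima = data.frame(value = -1, time = 1))
  expect_equal(extrema_summary(one)$avg_local_max,
               extrema_summary(one)$global_max)
  set.seed(2)
  v <- runif(20); w <- -runif(15)
  s <- extrema_summary(list(maxima = data.frame(value = v, time = seq_along(v)),
                            minima = data.frame(value = w, time = seq_along(w))))
  expect_equal(s$avg_local_max, mean(v))
  expect_equal(s$global_min, min(w))
  expect_error(extrema_summary(list(maxima = data.frame(value = numeric(0)),
                                    minima = data.frame(value = -1)),
                               require_complete = TRUE), "missing extrema")
})

test_that("quartile outliers use interpolated order statistics", {
  mask <- outlier_quartile(c(1, 2, 3, 4, 100))
  expect_equal(mask, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(outlier_quartile(rep(2, 6))))
  expect_error(outlier_quartile(1:3), "at least 4")
})

test_that("max-vs-mean outliers compare the peak to the mean of the rest", {
  o <- outlier_max_vs_mean(c(10, 2, 2, 2), c(1, 2, 3, 4))
  expect_true(o$is_outlier)
  expect_equal(o$mean_rest, 2)
  expect_equal(o$time, 1)
  expect_false(outlier_max_vs_mean(c(5, 5, 5), 1:3)$is_outlier)
  # scale invariance
  set.seed(3)
  v <- runif(10)
  expect_equal(outlier_max_vs_mean(v, 1:10)$is_outlier,
               outlier_max_vs_mean(1e3 * v, 1:10)$is_outlier)
  expect_error(outlier_max_vs_mean(5, 1), "at least 2")
  expect_error(outlier_max_vs_mean(c(-1, 2), 1:2), "all non-negative")
})

test_that("distribution monitor flags clutter bins and clamps the bound", {
  # 500 tiny maxima in bin 1, a few spread over bins 2-5
  values <- c(runif(500, 0.05, 0.95), runif(3, 1.05, 1.95),
              runif(2, 2.05, 2.95), runif(3, 3.05, 3.95), runif(2, 4.05, 4.95))
  ex <- data.frame(value = values)
  bound <- distribution_monitor(ex, "maxima", h = 1, limit = 5, clamp = 2)
  expect_equal(bound, 2) # bin-1 upper edge is 1, clamped up to 2
  # uniform counts: no outlier bin
  ex2 <- data.frame(value = runif(100, 0, 5))
  expect_null(distribution_monitor(ex2, "maxima", h = 1, limit = 5, clamp = 2))
  # minima side returns a negative bound no smaller in magnitude than the clamp
  exm <- data.frame(value = -values)
  bm <- distribution_monitor(exm, "minima", h = 1, limit = 5, clamp = 2)
  expect_lte(bm, -2)
  expect_error(distribution_monitor(ex, "maxima", h = 2, limit = 5, clamp = 2),
               "five bins")
})
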