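test_that("upward zero-crossings count strokes of a pure tone", {
  fs <- 10
  t <- seq(0, 100, by = 1 / fs)
  x <- 15 * sin(2 * pi * 0.15 * t)
  s <- detect_fluke_strokes(x, fs, t)
  expect_gte(nrow(s), 14)
  expect_lte(nrow(s), 16)
  expect_equal(stroke_frequency(s), 0.15, tolerance = 0.02)

  # zero signal and sub-gate signal produce no strokes
  expect_equal(nrow(detect_fluke_strokes(rep(0, 1000), fs)), 0)
  weak <- 2 * sin(2 * pi * 0.15 * t)   # below the 5 deg/s gate
  expect_equal(nrow(detect_fluke_strokes(weak, fs, t)), 0)

  # unfiltered-looking input warns
  set.seed(5)
  expect_warning(detect_fluke_strokes(rnorm(1000, sd = 30), fs),
                 "band-pass")
})

test_that("stroke count is invariant to a DC offset before band-passing", {
  fs <- 10
  t <- seq(0, 200, by = 1 / fs)
  # phase offset keeps crossings away from the series edges
  raw <- 15 * sin(2 * pi * 0.16 * t + 0.7)
  band0 <- butterworth_zero_lag(raw, fs, "pass", c(0.08, 0.2))
  band1 <- butterworth_zero_lag(raw + 40, fs, "pass", c(0.08, 0.2))
  n0 <- nrow(detect_fluke_strokes(band0, fs, t))
  n1 <- nrow(detect_fluke_strokes(band1, fs, t))
  expect_equal(n0, n1)
})

test_that("stroke frequency is the reciprocal mean inter-peak interval", {
  mk <- function(pt) structure(
    data.frame(peak_t = pt, depth = NA_real_,
               interval = c(NA, diff(pt)), freq = 1 / c(NA, diff(pt))),
    class = c("fluke_strokes", "data.frame"))
  expect_equal(stroke_frequency(mk(c(0, 5, 10, 15))), 0.2)
  expect_equal(stroke_frequency(mk(c(0, 4, 12))), 1 / 6)
  expect_true(is.na(stroke_frequency(mk(7))))
  # uniformly spaced peaks: exactly 1/spacing
  expect_equal(stroke_frequency(mk(seq(0, 90, by = 4.5))), 1 / 4.5)
  # windowing restricts the peaks used
  expect_equal(stroke_frequency(mk(c(0, 5, 10, 15, 100)), c(0, 20)), 0.2)
})

test_that("rolling fluke rate counts peaks in centred 30-s windows", {
  mk <- function(pt) data.frame(peak_t = pt)
  grid <- seq(0, 300, by = 10)
  r <- rolling_fluke_rate(mk(seq(0, 300, by = 5)), grid)
  expect_true(all(r[grid >= 15 & grid <= 285] %in% c(6, 7)))
  expect_equal(rolling_fluke_rate(mk(numeric(0)), grid), rep(0, length(grid)))
  # burst of 5 strokes in 10 s then silence
  rb <- rolling_fluke_rate(mk(seq(100, 108, by = 2)), grid)
  expect_equal(max(rb), 5)
  expect_equal(rb[grid > 140], rep(0, sum(grid > 140)))
})

# oracle: per-deployment z-scores, mirroring the documented outlier rule
scale_by <- function(pool) {
  unlist(lapply(split(pool$freq, pool$deployment_id),
                function(x) (x - mean(x)) / sd(x)), use.names = FALSE)
}

test_that("depth-strata model separates programmed gait frequencies", {
  set.seed(31)
  n <- 1000
  mkdep <- function(id, hours) {
    depth <- runif(2 * n, 5, 45)
    freq <- ifelse(depth <= 23, rnorm(2 * n, 0.192, 0.039),
                   rnorm(2 * n, 0.151, 0.024))
    data.frame(deployment_id = id, peak_t = seq_len(2 * n), depth = depth,
               freq = freq, hour = sample(hours, 2 * n, replace = TRUE))
  }
  pool <- rbind(mkdep("a", 8:11), mkdep("b", 10:14))
  fit <- depth_strata_model(pool)
  expect_lt(fit$estimate, 0)          # deep is slower
  expect_lt(fit$p_value, 0.01)
  expect_equal(unname(fit$medians_hz[["shallow"]]), 0.192, tolerance = 0.05)
  expect_equal(unname(fit$medians_hz[["deep"]]), 0.151, tolerance = 0.05)
  expect_equal(sum(fit$n_strokes), sum(abs(scale_by(pool)) <= 3))

  # degenerate: single deployment with no variance
  flat <- data.frame(deployment_id = "a", peak_t = 1:10, depth = 1:10,
                     freq = 0.15, hour = 12)
  expect_error(depth_strata_model(flat), "standardize")
})

test_that("strata model is well-calibrated under the null", {
  # identical distributions in both strata: effect within 2 SE of zero in
  # at least 90% of replicates
  ok <- 0
  for (rep_i in 1:100) {
    set.seed(400 + rep_i)
    n <- 400
    pool <- data.frame(
      deployment_id = sample(c("a", "b", "c"), n, replace = TRUE),
      peak_t = seq_len(n),
      depth = runif(n, 5, 45),
      freq = rnorm(n, 0.17, 0.04),
      hour = sample(9:14, n, replace = TRUE))
    fit <- depth_strata_model(pool)
    if (abs(fit$estimate) <= 2 * fit$se) ok <- ok + 1
  }
  expect_gte(ok, 90)
})
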