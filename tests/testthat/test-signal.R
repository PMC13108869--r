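test_that("zero-phase filtering passes DC, rejects out-of-band tones, and is
           time-reversal symmetric", {
  fs <- 10
  n <- 3000
  t <- (seq_len(n) - 1) / fs

  # DC through the low-pass
  expect_equal(butterworth_zero_lag(rep(3.7, n), fs, "low", 0.08),
               rep(3.7, n), tolerance = 1e-6)

  # 0.01 Hz tone through the fluke band-pass: > 90% attenuation
  slow <- sin(2 * pi * 0.01 * t)
  out <- butterworth_zero_lag(slow, fs, "pass", c(0.08, 0.2))
  mid <- 500:2500
  expect_lt(max(abs(out[mid])), 0.1)

  # in-band 0.15 Hz tone: peaks unshifted (zero lag)
  tone <- sin(2 * pi * 0.15 * t)
  bp <- butterworth_zero_lag(tone, fs, "pass", c(0.08, 0.2))
  cc <- ccf(bp[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # reversal symmetry: filter(reverse(x)) == reverse(filter(x))
  set.seed(1)
  x <- cumsum(rnorm(n))
  expect_equal(butterworth_zero_lag(rev(x), fs, "low", 0.08),
               rev(butterworth_zero_lag(x, fs, "low", 0.08)),
               tolerance = 1e-8)

  expect_error(butterworth_zero_lag(x, fs, "low", 6), "fs/2")
  expect_error(butterworth_zero_lag(x[1:10], fs, "low", 0.08), "too short")
})

test_that("orientation recovers constructed poses", {
  # level pose: static accel (0,0,-1) g, mag horizontal north
  o <- compute_orientation(matrix(c(0, 0, -1), 1), matrix(c(1, 0, 0), 1))
  expect_equal(o$pitch, 0)
  expect_equal(o$roll, 0)
  expect_equal(o$heading, 0)

  # oracle: rotate gravity with explicit rotation matrices and invert.
  # forward model: a_body = Rx(roll)^T Ry(-pitch)^T (0,0,-1)
  Rx <- function(p) matrix(c(1, 0, 0, 0, cos(p), -sin(p),
                             0, sin(p), cos(p)), 3, byrow = TRUE)
  Ry <- function(p) matrix(c(cos(p), 0, sin(p), 0, 1, 0,
                             -sin(p), 0, cos(p)), 3, byrow = TRUE)
  pose <- function(pitch_deg, roll_deg) {
    a <- t(Rx(roll_deg * pi / 180)) %*% t(Ry(-pitch_deg * pi / 180)) %*%
      c(0, 0, -1)
    matrix(as.numeric(a), 1)
  }
  # 30 degrees nose-down
  o <- compute_orientation(pose(-30, 0))
  expect_equal(o$pitch, -30, tolerance = 1e-8)
  expect_equal(o$roll, 0, tolerance = 1e-8)
  # combined pitch and roll
  for (pr in list(c(20, 45), c(-10, -120), c(55, 170))) {
    o <- compute_orientation(pose(pr[1], pr[2]))
    expect_equal(o$pitch, pr[1], tolerance = 1e-8)
    expect_equal(o$roll, pr[2], tolerance = 1e-8)
  }

  # inverse consistency: undoing the recovered rotation returns -e_z
  o <- compute_orientation(pose(25, 40))
  back <- Ry(-o$pitch * pi / 180) %*% Rx(o$roll * pi / 180) %*%
    t(pose(25, 40))
  expect_equal(as.numeric(back), c(0, 0, -1), tolerance = 1e-6)

  # miscalibrated magnitude triggers a warning
  expect_warning(compute_orientation(matrix(c(0, 0, -2), 1)), "calibration")
})

test_that("jerk follows the finite-difference norm in SI units", {
  # constant acceleration: no jerk
  a <- matrix(c(0.3, -0.2, -1), 10, 3, byrow = TRUE)
  expect_equal(compute_jerk(a, 10), rep(0, 10))

  # single-axis 1 g step at fs = 10: 1 * 9.81 * 10 at the step
  a <- cbind(c(rep(0, 5), rep(1, 5)), 0, -1)
  j <- compute_jerk(a, 10)
  expect_equal(j[6], 98.1)
  expect_equal(j[-6], rep(0, 9))

  # equal steps on all three axes: sqrt(3) times the single-axis value
  a3 <- cbind(c(rep(0, 5), rep(1, 5)), c(rep(0, 5), rep(1, 5)),
              c(rep(-1, 5), rep(0, 5)))
  expect_equal(compute_jerk(a3, 10)[6], sqrt(3) * 98.1)

  # finite-difference oracle on arbitrary input
  set.seed(2)
  a <- matrix(rnorm(60), 20, 3)
  oracle <- c(0, sqrt(rowSums(apply(a, 2, diff)^2)) * 9.81 * 10)
  expect_equal(compute_jerk(a, 10), oracle)

  # offset invariance: jerk is difference-based
  expect_equal(compute_jerk(a + 0.37, 10), compute_jerk(a, 10))

  expect_error(compute_jerk(a[1, , drop = FALSE], 10), "2 samples")
})

test_that("VeDBA is the SI norm of the dynamic component", {
  expect_equal(compute_vedba(matrix(0, 5, 3)), rep(0, 5))
  expect_equal(compute_vedba(matrix(c(0.1, 0, 0), 1)), 0.981)
  expect_equal(compute_vedba(matrix(c(0.1, 0.1, 0.1), 1)), 0.981 * sqrt(3))
  # norm oracle
  set.seed(3)
  a <- matrix(rnorm(30, sd = 0.05), 10, 3)
  expect_equal(compute_vedba(a), sqrt(rowSums(a^2)) * 9.81)
})

test_that("jiggle speed calibrates against OCDR on steep descents", {
  # noiseless-sensor deployment: jiggle amplitude proportional to true speed
  cfg <- sim_config(seed = 11, n_dives = 10, accel_noise_g = 0,
                    depth_noise = 0, gyro_noise = 0, mag_noise = 0)
  sim <- simulate_deployment(cfg)
  fit <- estimate_speed(sim$diary)
  expect_gt(fit$r, 0.9)
  # recovered speed within 10% of programmed transit speed mid-descent
  # (the qualifying steep-pitch samples)
  tr <- sim$truth
  rel_err <- vapply(seq_len(nrow(tr)), function(i) {
    mid <- tr$descent_start[i] + 0.5 * (tr$bottom_start[i] -
                                          tr$descent_start[i])
    sel <- fit$t > mid - 2 & fit$t < mid + 2
    abs(mean(fit$speed[sel]) - tr$transit_speed[i]) / tr$transit_speed[i]
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.10)

  # all-horizontal swimming: no qualifying OCDR samples -> calibration error
  flat <- make_toy_diary(4000, fs = 10, depth = 10)
  set.seed(4)
  flat$data$ax <- flat$data$ax + rnorm(4000, sd = 0.02)
  flat$data$ay <- flat$data$ay + rnorm(4000, sd = 0.02)
  flat$data$az <- flat$data$az + rnorm(4000, sd = 0.02)
  expect_error(estimate_speed(flat, speed_config(working_fs = 10)),
               "calibration")

  # predictions below the 0.9 m/s floor are flagged unreliable
  expect_true(all(!fit$reliable[fit$speed < 0.9]))
  expect_true(all(fit$reliable[fit$speed >= 0.9]))
})
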