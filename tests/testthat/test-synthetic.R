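test_that("identical seeds reproduce the deployment exactly", {
  a <- simulate_deployment(sim_config(seed = 71, n_dives = 5))
  b <- simulate_deployment(sim_config(seed = 71, n_dives = 5))
  expect_identical(a$diary$data, b$diary$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$events, b$events)
  c <- simulate_deployment(sim_config(seed = 72, n_dives = 5))
  expect_false(identical(a$diary$data, c$diary$data))
})

test_that("planned dives are recovered by the dive detector", {
  sim <- simulate_deployment(sim_config(seed = 73, n_dives = 20))
  work <- resample_diary(sim$diary, 10)
  d <- detect_dives(work$data$depth, 10, work$data$t)
  expect_equal(nrow(d), 20)
})

test_that("noise-free boundaries match the planned 5 m crossings within one
           sample", {
  cfg <- sim_config(seed = 74, n_dives = 8, accel_noise_g = 0,
                    depth_noise = 0, gyro_noise = 0, mag_noise = 0)
  sim <- simulate_deployment(cfg)
  work <- resample_diary(sim$diary, 10)
  d <- detect_dives(work$data$depth, 10, work$data$t)
  expect_equal(nrow(d), 8)
  expect_lte(max(abs(d$t_start - sim$truth$t_start_5m)), 0.1 + 1e-9)
  expect_lte(max(abs(d$t_end - sim$truth$t_end_5m)), 0.1 + 1e-9)
})

test_that("programmed feeding/non-feeding speed gap survives the pipeline", {
  cfg <- sim_config(seed = 75, n_dives = 16, no_video_fraction = 0,
                    accel_noise_g = 0, depth_noise = 0, gyro_noise = 0,
                    mag_noise = 0)
  sim <- simulate_deployment(cfg)
  pd <- process_deployment(sim$diary)
  dv <- detect_dives(pd$kin$depth, pd$fs, pd$kin$t)
  # truth bottom phases stand in for manual picking, isolating feature
  # extraction from the segmentation heuristic
  mb <- data.frame(dive_id = dv$dive_id, t_start = sim$truth$bottom_start,
                   t_end = sim$truth$bottom_end)
  dv <- segment_phases(dv, pd$kin$depth, pd$fs, pd$kin$t, manual_bottom = mb)
  strokes <- detect_fluke_strokes(pd$kin$gyro_y_band, pd$fs, pd$kin$t,
                                  pd$kin$depth)
  f <- dive_features(dv, pd$kin, pd$orientation, strokes)
  fd <- sim$truth$behavior == "Feeding"
  gap_true <- mean(sim$truth$mean_bottom_speed[!fd]) -
    mean(sim$truth$mean_bottom_speed[fd])
  gap_est <- mean(f$bottom_mean_speed[!fd]) - mean(f$bottom_mean_speed[fd])
  expect_lt(abs(gap_est - gap_true) / gap_true, 0.05)
})

test_that("gait-switch preset recovers programmed stroke frequencies by
           stratum", {
  cfg <- read_sim_config("mixed", seed = 76)
  sim <- simulate_deployment(cfg)
  pd <- process_deployment(sim$diary, speed = FALSE)
  strokes <- detect_fluke_strokes(pd$kin$gyro_y_band, pd$fs, pd$kin$t,
                                  pd$kin$depth)
  pool <- pool_strokes(stats::setNames(list(strokes),
                                       sim$diary$deployment_id),
                       start_time_utc = stats::setNames(
                         list(sim$diary$start_time_utc),
                         sim$diary$deployment_id))
  fit <- depth_strata_model(pool)
  expect_equal(unname(fit$medians_hz[["shallow"]]), 0.192, tolerance = 0.05)
  expect_equal(unname(fit$medians_hz[["deep"]]), 0.151, tolerance = 0.05)
})

test_that("infeasible plans and bad configs are rejected", {
  expect_error(sim_config(fs_working = 100, fs_native = 50))
  expect_error(sim_config(p_feeding = 1.4))
  expect_error(sim_config(fluke_shallow_hz = 8))
})

test_that("event coverage gaps produce NoVideo labels downstream", {
  cfg <- sim_config(seed = 77, n_dives = 12, no_video_fraction = 0.5)
  sim <- simulate_deployment(cfg)
  work <- resample_diary(sim$diary, 10)
  dv <- segment_phases(detect_dives(work$data$depth, 10, work$data$t),
                       work$data$depth, 10, work$data$t)
  lab <- assign_behavior(dv, sim$events)
  dive_labels <- lab$label[lab$scope == "dive"]
  expect_equal(sum(dive_labels == "NoVideo"), sum(!sim$truth$has_video))
})
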