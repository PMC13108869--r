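# Synthetic deployment simulator: generates complete fake tag deployments
# (multi-sensor diary, truth dive table, behaviour event log) with the
# statistical structure the analysis assumes — sub-Arctic fjord-style
# diving: mostly shallow (< 60 m) dives of ~1-11 min, fluke oscillation
# 0.12-0.2 Hz with a depth-dependent gait switch near 23 m, slower bottom
# speed with nose-down pitch and extra roll when feeding, and periodic
# jerk spikes with coincident speed increases during feeding bottoms.

#' Simulator configuration
#'
#' Defaults encode the study conditions the simulator emulates: bottom
#' swim speed 1.24 +/- 0.19 m/s feeding vs 1.64 +/- 0.54 m/s non-feeding,
#' feeding pitch -6.2 degrees, ~10 degree feeding roll oscillation, fluke
#' stroke frequency 0.192 Hz above / 0.151 Hz below the 23 m gait split,
#' feeding fraction 50/74 among videoed dives and 1/4 of dives with video
#' coverage.
#'
#' @param seed integer RNG seed (all randomness in the simulator flows from
#'   it; identical seed, identical output).
#' @param n_dives number of planned dives.
#' @param fs_native native sampling rate, Hz.
#' @param fs_working working rate the analysis runs at, Hz.
#' @param depth_meanlog,depth_sdlog,depth_range log-normal max-depth plan
#'   (m), clipped to `depth_range`.
#' @param duration_meanlog,duration_sdlog,duration_range log-normal total
#'   dive duration plan (minutes), clipped.
#' @param surface_range post-dive surface interval range, s (uniform).
#' @param descent_rate,ascent_rate mean vertical transit rates, m/s.
#' @param transit_speed_range per-dive swim speed during descent/ascent,
#'   m/s (uniform draw; the spread is what makes the jiggle/OCDR
#'   calibration identifiable).
#' @param p_feeding probability a dive is a feeding dive.
#' @param p_potential probability of a `PotentialForaging` dive.
#' @param no_video_fraction fraction of dives with no event coverage.
#' @param speed_feeding,speed_nonfeeding c(mean, sd) of bottom swim speed,
#'   m/s.
#' @param pitch_feeding,pitch_nonfeeding mean bottom pitch, degrees.
#' @param roll_amp_feeding,roll_amp_nonfeeding bottom roll oscillation
#'   amplitude, degrees.
#' @param fluke_shallow_hz,fluke_deep_hz,gait_split_m fluke-stroke
#'   frequency by depth stratum and the switch depth.
#' @param fluke_gyro_amp pitch-axis gyroscope fluke amplitude, deg/s.
#' @param fluke_accel_amp dynamic acceleration fluke amplitude, g.
#' @param jerk_spike_period_s,jerk_spike_g,jerk_spike_dur_s schedule and
#'   size of feeding-bottom jerk spikes (half-sine pulses on the surge
#'   axis).
#' @param speed_step_ms,speed_step_dur_s coincident speed increase after
#'   each spike.
#' @param jiggle_coef speed-proportional high-frequency acceleration noise,
#'   g per (m/s) — ties jiggle amplitude to true speed so the speed
#'   calibration is exercisable.
#' @param accel_noise_g,gyro_noise,mag_noise,depth_noise white sensor noise
#'   SDs.
#' @param mag_world world-frame magnetic field vector (arbitrary units).
#' @param start_time_utc deployment start.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_dives = 20, fs_native = 50,
                       fs_working = 10,
                       depth_meanlog = log(22), depth_sdlog = 0.55,
                       depth_range = c(6, 60),
                       duration_meanlog = log(4), duration_sdlog = 0.45,
                       duration_range = c(1, 11),
                       surface_range = c(20, 60),
                       descent_rate = 0.8, ascent_rate = 0.7,
                       transit_speed_range = c(1.2, 2.1),
                       p_feeding = 0.676, p_potential = 0.05,
                       no_video_fraction = 0.75,
                       speed_feeding = c(1.24, 0.191),
                       speed_nonfeeding = c(1.64, 0.542),
                       pitch_feeding = -6.2, pitch_nonfeeding = 0,
                       roll_amp_feeding = 10, roll_amp_nonfeeding = 3,
                       fluke_shallow_hz = 0.192, fluke_deep_hz = 0.151,
                       gait_split_m = 23,
                       fluke_gyro_amp = 20, fluke_accel_amp = 0.03,
                       jerk_spike_period_s = 45, jerk_spike_g = 0.25,
                       jerk_spike_dur_s = 0.4,
                       speed_step_ms = 0.3, speed_step_dur_s = 15,
                       jiggle_coef = 0.02, accel_noise_g = 0.008,
                       gyro_noise = 0.5, mag_noise = 0.005,
                       depth_noise = 0.05,
                       mag_world = c(0.3, 0, -0.9),
                       start_time_utc = as.POSIXct("2023-08-05 08:00:00",
                                                   tz = "UTC")) {
  cfg <- as.list(environment())
  stopifnot(cfg$fs_working <= cfg$fs_native,
            cfg$p_feeding >= 0, cfg$p_feeding <= 1,
            cfg$p_potential >= 0, cfg$p_feeding + cfg$p_potential <= 1,
            cfg$no_video_fraction >= 0, cfg$no_video_fraction <= 1,
            cfg$speed_feeding[2] >= 0, cfg$speed_nonfeeding[2] >= 0,
            cfg$fluke_shallow_hz > 0,
            cfg$fluke_shallow_hz < cfg$fs_working / 2,
            cfg$fluke_deep_hz > 0, cfg$fluke_deep_hz < cfg$fs_working / 2)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulator preset
#'
#' Presets are YAML files of [sim_config()] overrides; three scenario
#' presets ship with the package (`preset_mixed.yaml`,
#' `preset_shallow.yaml`, `preset_deep.yaml`) under `extdata`.
#'
#' @param path YAML file, or the bare name of a shipped preset
#'   (`"mixed"`, `"shallow"`, `"deep"`).
#' @param ... further overrides applied after the file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path, ...) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0("preset_", path, ".yaml"),
                           package = "divekin")
    if (shipped == "")
      stop("no such preset file or shipped preset: ", path, call. = FALSE)
    path <- shipped
  }
  over <- yaml::read_yaml(path)
  over <- utils::modifyList(over, list(...))
  if (!is.null(over$start_time_utc))
    over$start_time_utc <- as.POSIXct(over$start_time_utc, tz = "UTC")
  do.call(sim_config, over)
}

# plan the dives: depths, phase durations, behaviours, kinematic draws
plan_dives <- function(cfg) {
  n <- cfg$n_dives
  depth <- pmin(pmax(stats::rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog),
                     cfg$depth_range[1]), cfg$depth_range[2])
  dur_s <- 60 * pmin(pmax(stats::rlnorm(n, cfg$duration_meanlog,
                                        cfg$duration_sdlog),
                          cfg$duration_range[1]), cfg$duration_range[2])
  t_desc <- depth / cfg$descent_rate
  t_asc <- depth / cfg$ascent_rate
  dur_s <- pmax(dur_s, t_desc + t_asc + 30)   # guarantee a bottom phase
  t_bot <- dur_s - t_desc - t_asc

  u <- stats::runif(n)
  behavior <- ifelse(u < cfg$p_feeding, "Feeding",
                     ifelse(u < cfg$p_feeding + cfg$p_potential,
                            "PotentialForaging", "Travel"))
  feeding <- behavior == "Feeding"
  spd <- ifelse(feeding,
                stats::rnorm(n, cfg$speed_feeding[1], cfg$speed_feeding[2]),
                stats::rnorm(n, cfg$speed_nonfeeding[1],
                             cfg$speed_nonfeeding[2]))
  data.frame(
    dive_id = seq_len(n),
    max_depth = depth,
    t_descent = t_desc, t_bottom = t_bot, t_ascent = t_asc,
    surface_after = stats::runif(n, cfg$surface_range[1],
                                 cfg$surface_range[2]),
    behavior = behavior,
    bottom_speed = pmax(spd, 0.95),
    transit_speed = stats::runif(n, cfg$transit_speed_range[1],
                                 cfg$transit_speed_range[2]),
    bottom_pitch = ifelse(feeding, cfg$pitch_feeding, cfg$pitch_nonfeeding) +
      stats::rnorm(n, 0, 1.5),
    roll_amp = ifelse(feeding, cfg$roll_amp_feeding, cfg$roll_amp_nonfeeding),
    heading0 = stats::runif(n, 0, 360),
    heading_rate = stats::rnorm(n, 0, ifelse(feeding, 1.0, 0.25)),
    has_video = stats::runif(n) >= cfg$no_video_fraction)
}

#' Simulate a complete tag deployment
#'
#' Builds the native-rate multi-sensor diary for a planned sequence of
#' dives: depth from half-cosine-ramped trapezoids; acceleration as gravity
#' rotated by the programmed pitch/roll plus a fluke-coherent dynamic
#' oscillation, speed-proportional jiggle noise and scheduled jerk pulses
#' in feeding bottoms; pitch-axis gyroscope carrying the fluke sinusoid at
#' the depth-appropriate gait frequency; magnetometer consistent with the
#' programmed heading; and a behaviour event log covering the videoed
#' dives. All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `diary` (native-rate [diary_series()]), `truth`
#'   (per-dive plan and realized boundary times, including the 5 m crossing
#'   times of the noise-free depth), `events` (behaviour event data.frame)
#'   and `config`.
#' @export
simulate_deployment <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  plan <- plan_dives(cfg)
  fs <- cfg$fs_native
  n_dives <- nrow(plan)

  # assemble the segment timeline (durations in samples)
  seg_list <- list(data.frame(type = "surface", dive = 0, dur = 30,
                              stringsAsFactors = FALSE))
  for (i in seq_len(n_dives)) {
    seg_list[[length(seg_list) + 1]] <-
      data.frame(type = c("descent", "bottom", "ascent", "surface"),
                 dive = c(i, i, i, 0),
                 dur = c(plan$t_descent[i], plan$t_bottom[i],
                         plan$t_ascent[i], plan$surface_after[i]))
  }
  segs <- do.call(rbind, seg_list)
  segs$ns <- pmax(1L, round(segs$dur * fs))
  segs$end <- cumsum(segs$ns)
  segs$start <- segs$end - segs$ns + 1L
  n <- segs$end[nrow(segs)]
  t <- (seq_len(n) - 1) / fs

  depth_clean <- numeric(n)
  speed <- numeric(n)
  pitch <- numeric(n)
  roll <- numeric(n)
  heading <- numeric(n)
  fluking <- logical(n)
  hdg_last <- stats::runif(1, 0, 360)

  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    u <- (seq_along(idx) - 0.5) / length(idx)
    type <- segs$type[k]
    if (type == "surface") {
      depth_clean[idx] <- 0.2
      speed[idx] <- 0.5
      pitch[idx] <- 0
      roll[idx] <- 0
      heading[idx] <- hdg_last
      next
    }
    i <- segs$dive[k]
    D <- plan$max_depth[i]
    Tseg <- segs$ns[k] / fs
    v_tr <- plan$transit_speed[i]
    if (type == "descent") {
      depth_clean[idx] <- D * (1 - cos(pi * u)) / 2
      vrate <- D * pi * sin(pi * u) / (2 * Tseg)
      speed[idx] <- v_tr
      pitch[idx] <- -asin(pmin(vrate / v_tr, 0.95)) * 180 / pi
      roll[idx] <- 0
      hdg_last <- plan$heading0[i]
      heading[idx] <- hdg_last
    } else if (type == "bottom") {
      depth_clean[idx] <- D
      speed[idx] <- plan$bottom_speed[i]
      pitch[idx] <- plan$bottom_pitch[i]
      roll[idx] <- plan$roll_amp[i] *
        sin(2 * pi * (t[idx] - t[idx[1]]) / 40)
      heading[idx] <- (plan$heading0[i] +
                         plan$heading_rate[i] * (t[idx] - t[idx[1]])) %% 360
      hdg_last <- heading[idx[length(idx)]]
    } else {  # ascent
      depth_clean[idx] <- D * (1 + cos(pi * u)) / 2
      vrate <- D * pi * sin(pi * u) / (2 * Tseg)
      speed[idx] <- v_tr
      pitch[idx] <- asin(pmin(vrate / v_tr, 0.95)) * 180 / pi
      roll[idx] <- 0
      heading[idx] <- hdg_last
    }
    fluking[idx] <- TRUE
  }

  # jerk pulses + coincident speed steps in feeding bottom phases
  spike_times <- numeric(0)
  for (k in which(segs$type == "bottom")) {
    i <- segs$dive[k]
    if (plan$behavior[i] != "Feeding") next
    t0 <- t[segs$start[k]]; t1 <- t[segs$end[k]]
    last_ok <- t1 - cfg$speed_step_dur_s - 5
    if (t0 + cfg$jerk_spike_period_s > last_ok) next  # bottom too short
    spike_times <- c(spike_times,
                     seq(t0 + cfg$jerk_spike_period_s, last_ok,
                         by = cfg$jerk_spike_period_s))
  }
  spike_pulse <- numeric(n)
  for (st in spike_times) {
    idx <- which(t >= st & t < st + cfg$jerk_spike_dur_s)
    spike_pulse[idx] <- spike_pulse[idx] +
      cfg$jerk_spike_g * sin(pi * (t[idx] - st) / cfg$jerk_spike_dur_s)
    bidx <- which(t >= st & t < st + cfg$speed_step_dur_s)
    speed[bidx] <- speed[bidx] + cfg$speed_step_ms
  }

  # fluke oscillation: phase integrates the depth-dependent gait frequency
  freq <- ifelse(depth_clean <= cfg$gait_split_m,
                 cfg$fluke_shallow_hz, cfg$fluke_deep_hz)
  phase <- 2 * pi * cumsum(freq) / fs
  osc <- sin(phase) * fluking

  # channels
  a <- -pitch * pi / 180      # rotation about y in the forward model
  ph <- roll * pi / 180
  ca <- cos(a); sa <- sin(a); cr <- cos(ph); sr <- sin(ph)
  ax <- sa
  ay <- -sr * ca
  az <- -cr * ca

  noise_sd <- cfg$accel_noise_g + cfg$jiggle_coef * speed
  ax <- ax + cfg$fluke_accel_amp * osc + spike_pulse +
    stats::rnorm(n, 0, 1) * noise_sd
  ay <- ay + stats::rnorm(n, 0, 1) * noise_sd
  az <- az + 0.5 * cfg$fluke_accel_amp * osc + stats::rnorm(n, 0, 1) * noise_sd

  gy <- cfg$fluke_gyro_amp * osc + stats::rnorm(n, 0, cfg$gyro_noise)
  gx <- stats::rnorm(n, 0, cfg$gyro_noise)
  gz <- stats::rnorm(n, 0, cfg$gyro_noise)

  # magnetometer consistent with heading (heading = -yaw about z-up)
  psi <- -heading * pi / 180
  mw <- cfg$mag_world
  # m_body = Rx(roll)^T Ry(a)^T Rz(psi)^T m_world
  m1w <- cos(psi) * mw[1] + sin(psi) * mw[2]
  m2w <- -sin(psi) * mw[1] + cos(psi) * mw[2]
  m3w <- mw[3]
  m1p <- ca * m1w - sa * m3w
  m2p <- m2w
  m3p <- sa * m1w + ca * m3w
  mx <- m1p
  my <- cr * m2p + sr * m3p
  mz <- -sr * m2p + cr * m3p
  mx <- mx + stats::rnorm(n, 0, cfg$mag_noise)
  my <- my + stats::rnorm(n, 0, cfg$mag_noise)
  mz <- mz + stats::rnorm(n, 0, cfg$mag_noise)

  depth <- pmax(depth_clean + stats::rnorm(n, 0, cfg$depth_noise), -0.4)

  diary <- diary_series(
    data.frame(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz,
               mx = mx, my = my, mz = mz, depth = depth),
    fs = fs, deployment_id = sprintf("sim%04d", cfg$seed),
    start_time_utc = cfg$start_time_utc)

  # truth table: realized phase boundaries and noise-free 5 m crossings
  truth <- plan
  for (col in c("descent_start", "bottom_start", "bottom_end", "ascent_end",
                "t_start_5m", "t_end_5m"))
    truth[[col]] <- NA_real_
  truth$mean_bottom_speed <- NA_real_
  for (i in seq_len(n_dives)) {
    ks <- which(segs$dive == i)
    truth$descent_start[i] <- t[segs$start[ks[1]]]
    truth$bottom_start[i] <- t[segs$start[ks[2]]]
    truth$bottom_end[i] <- t[segs$end[ks[2]]]
    truth$ascent_end[i] <- t[segs$end[ks[3]]]
    didx <- segs$start[ks[1]]:segs$end[ks[3]]
    deeper <- didx[depth_clean[didx] > 5]
    if (length(deeper) > 0) {
      truth$t_start_5m[i] <- t[deeper[1]]
      truth$t_end_5m[i] <- t[deeper[length(deeper)]]
    }
    # realized mean (includes the post-spike speed boosts), the proper
    # reference for recovered bottom speeds
    truth$mean_bottom_speed[i] <- mean(speed[segs$start[ks[2]]:segs$end[ks[2]]])
  }

  events <- truth[truth$has_video, , drop = FALSE]
  events <- if (nrow(events) > 0)
    data.frame(deployment_id = diary$deployment_id,
               label = ifelse(events$behavior == "PotentialForaging",
                              "PotentialForaging",
                              ifelse(events$behavior == "Feeding",
                                     "Feeding", "Travel")),
               start_s = events$descent_start - 2,
               end_s = events$ascent_end + 2)
  else data.frame(deployment_id = character(0), label = character(0),
                  start_s = numeric(0), end_s = numeric(0))

  list(diary = diary, truth = truth, events = events, config = cfg)
}

#' Simulate a dive-level feature table
#'
#' Draws per-dive classifier features directly from behaviour-conditioned
#' distributions (the same kinematic signatures the deployment simulator
#' programs), with a deployment random intercept on the log-odds of
#' feeding. This feature-level generator exists for fast, targeted checks
#' of the model-fitting stage; it bypasses the sensor pipeline entirely.
#'
#' @param n_dives total dives.
#' @param n_deployments number of deployments (random-intercept groups).
#' @param p_feeding marginal feeding probability.
#' @param group_sd SD of the deployment intercept on the logit scale.
#' @param seed RNG seed.
#' @return data.frame with the bottom-phase features, `tod`, `tod_hour`,
#'   `deployment_id`, `label` and `feeding`.
#' @export
simulate_dive_features <- function(n_dives = 200, n_deployments = 10,
                                   p_feeding = 0.5, group_sd = 0.5,
                                   seed = 1L) {
  set.seed(seed)
  dep <- sprintf("dep%02d", sample.int(n_deployments, n_dives, replace = TRUE))
  u <- stats::rnorm(n_deployments, 0, group_sd)
  names(u) <- sprintf("dep%02d", seq_len(n_deployments))
  p <- stats::plogis(stats::qlogis(p_feeding) + u[dep])
  feeding <- stats::rbinom(n_dives, 1, p)
  f <- feeding == 1
  rnorm2 <- function(cond, m1, s1, m0, s0)
    ifelse(cond, stats::rnorm(n_dives, m1, s1), stats::rnorm(n_dives, m0, s0))
  # feeding skews earlier in the day; distributions overlap substantially
  # so single features only moderately separate the classes
  hour <- (rnorm2(f, 9, 5, 13, 5)) %% 24
  data.frame(
    dive_id = seq_len(n_dives),
    deployment_id = dep,
    bottom_mean_speed = pmax(0.3, rnorm2(f, 1.24, 0.191, 1.64, 0.542)),
    bottom_peak_jerk = pmax(0, rnorm2(f, 0.141, 0.148, 0.094, 0.070)),
    bottom_mean_pitch = rnorm2(f, -6.2, 7.68, 0, 7.68),
    bottom_mean_roll = rnorm2(f, -5.4, 6, 0, 6),
    bottom_speed_change = rnorm2(f, 0.15, 0.15, -0.08, 0.15),
    bottom_fluke_rate = pmax(0, rnorm2(f, 0.191 * 30, 1.2, 0.172 * 30, 1.2)),
    tod_hour = hour,
    tod = encode_time_of_day(hour),
    label = ifelse(f, "Feeding", "Travel"),
    feeding = feeding)
}

#' Simulate generic random-intercept logistic data
#'
#' Ground-truth generator for parameter-recovery checks of the GLMM fitter:
#' standard-normal covariates, known coefficients, Gaussian group
#' intercepts, Bernoulli response.
#'
#' @param n observations.
#' @param n_groups number of groups.
#' @param beta0 intercept.
#' @param beta named vector of slopes (names become covariate columns).
#' @param group_sd random-intercept SD.
#' @param seed RNG seed.
#' @return data.frame with the covariates, `deployment_id`, `feeding`;
#'   attribute `truth` holds the generating parameters.
#' @export
simulate_glmm_data <- function(n = 400, n_groups = 10, beta0 = 0.5,
                               beta = c(x = -2), group_sd = 0.5, seed = 1L) {
  set.seed(seed)
  g <- sprintf("g%02d", sample.int(n_groups, n, replace = TRUE))
  u <- stats::rnorm(n_groups, 0, group_sd)
  names(u) <- sprintf("g%02d", seq_len(n_groups))
  X <- matrix(stats::rnorm(n * length(beta)), n,
              dimnames = list(NULL, names(beta)))
  eta <- beta0 + as.numeric(X %*% beta) + u[g]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  out <- data.frame(X, deployment_id = g, feeding = y)
  attr(out, "truth") <- c(`(Intercept)` = beta0, beta, group_sd = group_sd)
  out
}
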