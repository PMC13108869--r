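# Filtering, body orientation, and the scalar kinematic series derived from
# the inertial channels: jerk, VeDBA, band-passed pitch-axis rotation rate,
# and the tag-jiggle swim-speed proxy.

# forward-backward filtering with odd-reflection padding: plain
# forward-backward application starts from zero state, and at the very low
# normalized cutoffs used here its startup transient would bleed far into
# the data. Padding long enough for the transient to die in the pads makes
# the interior exact.
filtfilt_refl <- function(bf, x, pad) {
  n <- length(x)
  pad <- as.integer(max(1L, min(n - 1L, pad)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter and applies it forward-backward
#' (zero phase shift, so filtered peaks stay aligned with raw peaks).
#' Defaults reproduce the two filters used throughout the pipeline:
#' a 2nd-order 0.08 Hz low-pass isolating the static (gravity/orientation)
#' component, and a 2nd-order 0.08-0.2 Hz band-pass isolating fluke strokes
#' on the pitch-axis gyroscope.
#'
#' @param x numeric series, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param kind `"low"` or `"pass"` (band-pass).
#' @param fc cutoff in Hz: scalar for low-pass, length-2 for band-pass.
#' @param order filter order (applied twice, so effective order doubles).
#' @return filtered series, same length as `x`.
#' @export
butterworth_zero_lag <- function(x, fs, kind = c("low", "pass"),
                                 fc = if (match.arg(kind) == "low") 0.08
                                      else c(0.08, 0.2),
                                 order = 2) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (any(fc <= 0) || any(fc >= nyq))
    stop("cutoff must lie strictly inside (0, fs/2)", call. = FALSE)
  if (kind == "pass" && length(fc) != 2)
    stop("band-pass needs two cutoff frequencies", call. = FALSE)
  # forward-backward filtering needs a comfortable margin over the filter's
  # effective impulse length
  min_len <- max(3 * (order * 3 + 1), ceiling(3 * fs / min(fc)))
  if (length(x) < min_len)
    stop("series too short (", length(x), " samples) for cutoff ",
         min(fc), " Hz at ", fs, " Hz; need >= ", min_len, call. = FALSE)
  bf <- signal::butter(order, fc / nyq, type = kind)
  as.numeric(filtfilt_refl(bf, x, round(10 * fs / min(fc))))
}

#' Body orientation from static acceleration and magnetic field
#'
#' Recovers pitch, roll and heading from the low-passed (gravity-dominated)
#' acceleration and magnetometer channels. Whale frame: x forward, y left,
#' z up; a level whale reads static acceleration `(0, 0, -1)` g. Pitch is
#' positive nose-up, roll positive right-side-down, heading in degrees
#' clockwise from north in `[0, 360)` after tilt compensation and
#' declination correction.
#'
#' @param accel_static 3-column matrix/data.frame (`ax,ay,az`, g), low-passed.
#' @param mag_static 3-column matrix/data.frame, same filtering.
#' @param declination magnetic declination in degrees (added to magnetic
#'   heading to give true heading).
#' @return data.frame with `pitch`, `roll`, `heading` in degrees.
#' @export
compute_orientation <- function(accel_static, mag_static = NULL,
                                declination = 0) {
  a <- as.matrix(accel_static)
  stopifnot(ncol(a) == 3)
  nrm <- sqrt(rowSums(a^2))
  frac_bad <- mean(nrm < 0.5 | nrm > 1.5)
  if (frac_bad > 0.10)
    warning(sprintf(paste0("static acceleration norm outside [0.5, 1.5] g ",
                           "for %.0f%% of samples: check calibration or ",
                           "low-pass settings"), 100 * frac_bad),
            call. = FALSE)
  an <- a / pmax(nrm, 1e-12)
  pitch <- -asin(pmin(1, pmax(-1, an[, 1])))
  roll <- atan2(-an[, 2], -an[, 3])

  heading <- rep(NA_real_, nrow(a))
  if (!is.null(mag_static)) {
    m <- as.matrix(mag_static)
    stopifnot(ncol(m) == 3, nrow(m) == nrow(a))
    # rotate the body-frame magnetic vector back to the horizontal plane
    # (undo roll about x, then the pitch rotation about y)
    cr <- cos(roll); sr <- sin(roll)
    alpha <- -pitch            # rotation angle about y in the forward model
    ca <- cos(alpha); sa <- sin(alpha)
    # m_lev = Ry(alpha) %*% Rx(roll) %*% m, per sample
    m1 <- m[, 1]
    m2 <- cr * m[, 2] - sr * m[, 3]
    m3 <- sr * m[, 2] + cr * m[, 3]
    mx_lev <- ca * m1 + sa * m3
    my_lev <- m2
    heading <- (atan2(my_lev, mx_lev) * 180 / pi + declination) %% 360
  }
  data.frame(pitch = pitch * 180 / pi,
             roll = roll * 180 / pi,
             heading = heading)
}

#' Jerk from tri-axial acceleration
#'
#' The norm of the sample-to-sample acceleration difference across all three
#' axes, converted to SI: `jerk[i] = sqrt(dax^2 + day^2 + daz^2) * 9.81 * fs`
#' (m/s^3). Differencing across the sampling interval makes this the
#' discrete time-derivative of acceleration; spikes mark rapid events such
#' as hypothesised mouth closures. The first sample is 0 by convention.
#'
#' @param accel 3-column matrix/data.frame of acceleration in g.
#' @param fs sampling rate in Hz.
#' @return numeric series in m/s^3, same length as input.
#' @export
compute_jerk <- function(accel, fs) {
  a <- as.matrix(accel)
  stopifnot(ncol(a) == 3)
  if (nrow(a) < 2)
    stop("jerk needs at least 2 samples", call. = FALSE)
  d <- diff(a)
  c(0, sqrt(rowSums(d^2)) * 9.81 * fs)
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' The norm of the dynamic acceleration component across all three axes in
#' SI units: `sqrt(ax_dyn^2 + ay_dyn^2 + az_dyn^2) * 9.81` (m/s^2). The
#' dynamic component is the raw acceleration minus its low-passed static
#' component (see [butterworth_zero_lag()]). VeDBA is a standard proxy for
#' energy expenditure.
#'
#' @param accel_dynamic 3-column matrix/data.frame of dynamic acceleration
#'   in g.
#' @return numeric series in m/s^2.
#' @export
compute_vedba <- function(accel_dynamic) {
  a <- as.matrix(accel_dynamic)
  stopifnot(ncol(a) == 3)
  sqrt(rowSums(a^2)) * 9.81
}

#' Default configuration for the jiggle speed proxy
#'
#' @param highpass_hz corner of the high-pass isolating tag jiggle, Hz
#'   (capped below the native Nyquist).
#' @param window_s RMS window length, seconds.
#' @param pitch_min minimum absolute pitch (degrees) for a sample to enter
#'   the OCDR calibration; depth rate only constrains speed at steep pitch.
#' @param speed_floor minimum detectable jiggle speed, m/s; predictions
#'   below it are flagged unreliable.
#' @param min_calibration_samples minimum qualifying samples for the
#'   regression.
#' @param min_depth_rate minimum |depth rate| (m/s) for OCDR validity.
#' @param jiggle_smooth_s running-mean length (s) applied to the jiggle
#'   series before calibration and prediction; short RMS windows make
#'   jiggle a noisy regressor, which would attenuate the fitted slope
#'   (regression dilution), so the jiggle is smoothed on the time scale
#'   over which swim speed actually varies.
#' @param log_log fit the calibration on log-log axes (default) or linear.
#' @param working_fs rate (Hz) of the output speed series.
#' @export
speed_config <- function(highpass_hz = 10, window_s = 0.5, pitch_min = 30,
                         speed_floor = 0.9, min_calibration_samples = 25,
                         min_depth_rate = 0.2, jiggle_smooth_s = 10,
                         log_log = TRUE, working_fs = 10) {
  list(highpass_hz = highpass_hz, window_s = window_s, pitch_min = pitch_min,
       speed_floor = speed_floor,
       min_calibration_samples = min_calibration_samples,
       min_depth_rate = min_depth_rate, jiggle_smooth_s = jiggle_smooth_s,
       log_log = log_log, working_fs = working_fs)
}

#' Swim speed from tag jiggle calibrated against OCDR
#'
#' High-frequency accelerometer vibration ("jiggle") scales with flow speed
#' over the tag. The RMS jiggle amplitude (high-passed acceleration norm in
#' sliding windows at the native rate) is regressed against
#' orientation-corrected depth rate (OCDR = |d depth / dt| / |sin(pitch)|),
#' which is a valid speed reference only at steep pitch. The fitted relation
#' then predicts speed everywhere from jiggle alone. Predictions below the
#' minimum detectable jiggle speed (~0.9 m/s) are flagged unreliable.
#'
#' @param series native-rate [diary_series()] (jiggle needs the full
#'   bandwidth; the speed series is returned on the working grid).
#' @param cfg a [speed_config()].
#' @return list with `t`, `speed` (m/s), `reliable` (logical),
#'   `jiggle`, `coefficients` of the calibration fit, `r` (correlation on
#'   the fitted axes) and `n_calibration`.
#' @export
estimate_speed <- function(series, cfg = speed_config()) {
  stopifnot(inherits(series, "diary_series"))
  fs <- series$fs
  wfs <- cfg$working_fs
  if (wfs > fs) stop("working_fs exceeds native rate", call. = FALSE)

  # jiggle at native rate: high-pass each axis, norm, windowed RMS
  hp_corner <- min(cfg$highpass_hz, 0.8 * fs / 2)
  bf <- signal::butter(2, hp_corner / (fs / 2), type = "high")
  hp <- vapply(c("ax", "ay", "az"),
               function(ch) filtfilt_refl(bf, series$data[[ch]],
                                          round(10 * fs / hp_corner)),
               numeric(nrow(series$data)))
  sq <- rowSums(hp^2)
  half <- max(1L, round(cfg$window_s * fs / 2))
  csq <- cumsum(c(0, sq))
  n <- length(sq)
  # working-grid sample indices in the native series
  step <- round(fs / wfs)
  idx <- seq(1L, n, by = step)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  jiggle <- sqrt((csq[hi + 1L] - csq[lo]) / (hi - lo + 1L))
  if (!is.null(cfg$jiggle_smooth_s) && cfg$jiggle_smooth_s > 0) {
    w <- max(1L, round(cfg$jiggle_smooth_s * wfs))
    cj <- cumsum(c(0, jiggle))
    nj <- length(jiggle)
    jlo <- pmax(0L, seq_len(nj) - 1L - w %/% 2L)
    jhi <- pmin(nj, seq_len(nj) + w %/% 2L)
    jiggle <- (cj[jhi + 1L] - cj[jlo + 1L]) / (jhi - jlo)
  }

  # working-rate depth and pitch for OCDR
  work <- resample_diary(series, wfs)
  static <- vapply(c("ax", "ay", "az"),
                   function(ch) butterworth_zero_lag(work$data[[ch]], wfs,
                                                     "low", 0.08),
                   numeric(nrow(work$data)))
  orient <- compute_orientation(static)
  pitch <- orient$pitch
  # depth rate: low-pass the depth channel and use a 1-s central
  # difference; raw sample-to-sample differencing amplifies TDR noise
  dsm <- butterworth_zero_lag(work$data$depth, wfs, "low",
                              min(0.2, 0.4 * wfs / 2))
  hw <- max(1L, round(wfs / 2))
  nw <- length(dsm)
  ddepth <- rep(NA_real_, nw)
  ii <- (hw + 1):(nw - hw)
  ddepth[ii] <- (dsm[ii + hw] - dsm[ii - hw]) * wfs / (2 * hw)
  m <- min(length(jiggle), nrow(work$data))
  jiggle <- jiggle[seq_len(m)]
  pitch <- pitch[seq_len(m)]
  ddepth <- ddepth[seq_len(m)]
  tgrid <- work$data$t[seq_len(m)]

  qual <- !is.na(ddepth) &
    abs(pitch) >= cfg$pitch_min &
    abs(ddepth) >= cfg$min_depth_rate &
    jiggle > 0
  ocdr <- abs(ddepth) / pmax(abs(sin(pitch * pi / 180)), 1e-6)
  n_cal <- sum(qual)
  if (n_cal < cfg$min_calibration_samples)
    stop("speed calibration failed: only ", n_cal,
         " qualifying steep-pitch samples (need ",
         cfg$min_calibration_samples, ")", call. = FALSE)

  if (cfg$log_log) {
    fit <- stats::lm(log(ocdr[qual]) ~ log(jiggle[qual]))
    b <- stats::coef(fit)
    speed <- exp(b[1] + b[2] * log(pmax(jiggle, 1e-12)))
    r <- stats::cor(log(ocdr[qual]), log(jiggle[qual]))
  } else {
    fit <- stats::lm(ocdr[qual] ~ jiggle[qual])
    b <- stats::coef(fit)
    speed <- pmax(0, b[1] + b[2] * jiggle)
    r <- stats::cor(ocdr[qual], jiggle[qual])
  }
  list(t = tgrid, speed = as.numeric(speed),
       reliable = as.numeric(speed) >= cfg$speed_floor,
       jiggle = jiggle,
       coefficients = stats::setNames(as.numeric(b),
                                      c("intercept", "slope")),
       r = r, n_calibration = n_cal)
}

#' Full kinematic processing of a deployment
#'
#' Convenience driver: resamples the native diary to the working rate,
#' separates static and dynamic acceleration with the 0.08 Hz zero-phase
#' low-pass, recomputes orientation from the static components, computes
#' jerk and VeDBA, band-passes the pitch-axis gyroscope to the fluke band
#' (0.08-0.2 Hz), and (optionally) calibrates the jiggle speed proxy.
#'
#' @param series native-rate [diary_series()].
#' @param working_fs working rate, Hz (default 10).
#' @param declination magnetic declination, degrees.
#' @param speed `TRUE` to run the jiggle/OCDR speed calibration (falls back
#'   to `NA` speed with a warning if calibration fails).
#' @param speed_cfg a [speed_config()].
#' @return list with the working-rate diary (`work`), `orientation`
#'   (pitch/roll/heading data.frame), and `kin` data.frame with
#'   `t, depth, jerk, vedba, gyro_y_band, speed, speed_reliable`.
#' @export
process_deployment <- function(series, working_fs = 10, declination = 0,
                               speed = TRUE, speed_cfg = speed_config(
                                 working_fs = working_fs)) {
  work <- resample_diary(series, working_fs)
  n <- nrow(work$data)
  static <- vapply(c("ax", "ay", "az"),
                   function(ch) butterworth_zero_lag(work$data[[ch]],
                                                     working_fs, "low", 0.08),
                   numeric(n))
  mstatic <- vapply(c("mx", "my", "mz"),
                    function(ch) butterworth_zero_lag(work$data[[ch]],
                                                      working_fs, "low", 0.08),
                    numeric(n))
  orient <- compute_orientation(static, mstatic, declination)
  dyn <- as.matrix(work$data[, c("ax", "ay", "az")]) - static
  kin <- data.frame(
    t = work$data$t,
    depth = work$data$depth,
    jerk = compute_jerk(work$data[, c("ax", "ay", "az")], working_fs),
    vedba = compute_vedba(dyn),
    gyro_y_band = butterworth_zero_lag(work$data$gy, working_fs, "pass",
                                       c(0.08, 0.2)),
    speed = NA_real_,
    speed_reliable = FALSE)
  speed_fit <- NULL
  if (speed) {
    speed_fit <- tryCatch(estimate_speed(series, speed_cfg),
                          error = function(e) {
                            warning(conditionMessage(e), call. = FALSE)
                            NULL
                          })
    if (!is.null(speed_fit)) {
      m <- min(n, length(speed_fit$speed))
      kin$speed[seq_len(m)] <- speed_fit$speed[seq_len(m)]
      kin$speed_reliable[seq_len(m)] <- speed_fit$reliable[seq_len(m)]
    }
  }
  list(work = work, orientation = orient, kin = kin, speed_fit = speed_fit,
       fs = working_fs)
}
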