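# Per-dive, per-phase kinematic predictors feeding the feeding classifier:
# phase means of speed/pitch/roll/VeDBA, circular heading variance, fluke
# statistics, descent/ascent rates, the bottom-phase jerk peak with its
# +/-20 s speed and fluke-rate deltas, and the cyclical time-of-day
# encoding.

#' Cyclical time-of-day encoding
#'
#' Maps clock time onto a single dimensionless cyclical covariate:
#' `cos(2*pi*t/24) + sin(2*pi*t/24)` with `t` in decimal hours. The sum is
#' 24 h-periodic, bounded by +/- sqrt(2), maximal at 03:00 and minimal at
#' 15:00. Set `components = TRUE` to obtain the two components separately
#' (the summed scalar is not invertible to clock time).
#'
#' @param time POSIXct timestamp(s), or numeric decimal hours in `[0, 24)`.
#' @param components return a two-column data.frame (`tod_cos`, `tod_sin`)
#'   instead of their sum.
#' @return numeric vector (or data.frame if `components`).
#' @export
encode_time_of_day <- function(time, components = FALSE) {
  if (inherits(time, "POSIXt")) {
    lt <- as.POSIXlt(time, tz = "UTC")
    hours <- lt$hour + lt$min / 60 + lt$sec / 3600
  } else {
    hours <- as.numeric(time) %% 24
  }
  ang <- 2 * pi * hours / 24
  if (components) data.frame(tod_cos = cos(ang), tod_sin = sin(ang))
  else cos(ang) + sin(ang)
}

#' Circular variance of headings
#'
#' One minus the mean resultant length of the heading unit vectors, scaled
#' to squared-degree-equivalent units (`2 * (1 - R)` in radians^2, converted
#' to deg^2). Arithmetic variance is meaningless across the 0/360 wrap.
#'
#' @param heading_deg headings in degrees.
#' @return non-negative scalar, deg^2-equivalent.
#' @export
circular_variance_deg2 <- function(heading_deg) {
  h <- heading_deg[!is.na(heading_deg)] * pi / 180
  if (length(h) == 0) return(NA_real_)
  R <- sqrt(mean(cos(h))^2 + mean(sin(h))^2)
  2 * (1 - R) * (180 / pi)^2
}

phase_mean <- function(x, t, t0, t1) {
  if (is.na(t0) || is.na(t1)) return(NA_real_)
  sel <- t >= t0 & t <= t1
  if (!any(sel)) return(NA_real_)
  mean(x[sel], na.rm = TRUE)
}

#' Bottom-phase jerk peak and its before/after deltas
#'
#' Locates the jerk maximum within the bottom phase (earliest index on
#' ties). The peak jerk is the maximum minus the median jerk over the phase
#' (robust to between-individual baseline differences). Speed change is the
#' mean speed in the 20 s after the peak minus the 20 s before (peak sample
#' excluded, windows clipped to the phase); the fluke-rate change is the
#' analogous delta on the rolling 30-s fluke rate. Roll at the peak is also
#' reported.
#'
#' @param kin kinematic data.frame with `t`, `jerk`, `speed`.
#' @param roll roll series (deg) aligned with `kin$t`.
#' @param fluke_rate rolling fluke rate aligned with `kin$t` (counts per
#'   30 s); see [rolling_fluke_rate()].
#' @param bottom c(start, end) of the bottom phase, seconds.
#' @param halfwidth window half-width, seconds (default 20).
#' @return list `peak_jerk`, `speed_change`, `fluke_rate_change`,
#'   `roll_at_peak`, `t_peak`; all `NA` if the phase has < 2 samples.
#' @export
peak_jerk_deltas <- function(kin, roll = NULL, fluke_rate = NULL,
                             bottom, halfwidth = 20) {
  na_out <- list(peak_jerk = NA_real_, speed_change = NA_real_,
                 fluke_rate_change = NA_real_, roll_at_peak = NA_real_,
                 t_peak = NA_real_)
  if (any(is.na(bottom))) return(na_out)
  sel <- which(kin$t >= bottom[1] & kin$t <= bottom[2])
  if (length(sel) < 2) return(na_out)
  j <- kin$jerk[sel]
  ipk <- sel[which.max(j)]        # which.max takes the earliest tie
  tpk <- kin$t[ipk]
  peak_jerk <- max(j) - stats::median(j)

  before <- kin$t >= max(bottom[1], tpk - halfwidth) & kin$t < tpk
  after <- kin$t > tpk & kin$t <= min(bottom[2], tpk + halfwidth)
  delta <- function(x) {
    if (!any(before) || !any(after)) return(NA_real_)
    mean(x[after], na.rm = TRUE) - mean(x[before], na.rm = TRUE)
  }
  list(peak_jerk = peak_jerk,
       speed_change = delta(kin$speed),
       fluke_rate_change = if (is.null(fluke_rate)) NA_real_
                           else delta(fluke_rate),
       roll_at_peak = if (is.null(roll)) NA_real_ else roll[ipk],
       t_peak = tpk)
}

#' Per-dive kinematic feature table
#'
#' Assembles the model-ready table: for each dive, per-phase means of
#' speed, pitch, roll and VeDBA, circular heading variance, fluke-stroke
#' frequency and mean rolling fluke rate, descent/ascent vertical rates,
#' the bottom-phase jerk peak with its +/-20 s speed and fluke-rate deltas,
#' the cyclical time-of-day covariate of the dive start, and (optionally)
#' the dive-level behaviour label.
#'
#' @param dives segmented dive table from [segment_phases()].
#' @param kin kinematic data.frame (`t, depth, jerk, vedba, speed`) from
#'   [process_deployment()].
#' @param orient orientation data.frame (`pitch, roll, heading`) aligned
#'   with `kin`.
#' @param strokes `fluke_strokes` set for the deployment.
#' @param labels optional label table from [assign_behavior()]; the
#'   dive-scope label is attached.
#' @param deployment_id identifier stored per row.
#' @param start_time_utc POSIXct of `t = 0` (for time-of-day encoding).
#' @return data.frame, one row per dive.
#' @export
dive_features <- function(dives, kin, orient, strokes, labels = NULL,
                          deployment_id = "unknown",
                          start_time_utc = as.POSIXct("2023-08-05 12:00:00",
                                                      tz = "UTC")) {
  frate <- rolling_fluke_rate(strokes, kin$t)
  phases <- c("descent", "bottom", "ascent")
  rows <- lapply(seq_len(nrow(dives)), function(i) {
    dv <- dives[i, ]
    row <- data.frame(dive_id = dv$dive_id, deployment_id = deployment_id,
                      duration_min = dv$duration_min,
                      max_depth = dv$max_depth, shape = dv$shape)
    for (ph in phases) {
      t0 <- dv[[paste0(ph, "_start")]]
      t1 <- dv[[paste0(ph, "_end")]]
      sel <- !is.na(t0) & !is.na(t1)
      row[[paste0(ph, "_mean_speed")]] <- phase_mean(kin$speed, kin$t, t0, t1)
      row[[paste0(ph, "_mean_pitch")]] <- phase_mean(orient$pitch, kin$t, t0, t1)
      row[[paste0(ph, "_mean_roll")]] <- phase_mean(orient$roll, kin$t, t0, t1)
      row[[paste0(ph, "_mean_vedba")]] <- phase_mean(kin$vedba, kin$t, t0, t1)
      row[[paste0(ph, "_heading_var")]] <- if (sel)
        circular_variance_deg2(orient$heading[kin$t >= t0 & kin$t <= t1])
      else NA_real_
      row[[paste0(ph, "_fluke_freq")]] <- if (sel)
        stroke_frequency(strokes, c(t0, t1)) else NA_real_
      row[[paste0(ph, "_fluke_rate")]] <- phase_mean(frate, kin$t, t0, t1)
    }
    # vertical transit rates: depth change across the phase / duration
    rate <- function(t0, t1) {
      if (is.na(t0) || is.na(t1) || t1 <= t0) return(NA_real_)
      d0 <- stats::approx(kin$t, kin$depth, xout = t0, rule = 2)$y
      d1 <- stats::approx(kin$t, kin$depth, xout = t1, rule = 2)$y
      abs(d1 - d0) / (t1 - t0)
    }
    row$descent_rate <- rate(dv$descent_start, dv$descent_end)
    row$ascent_rate <- rate(dv$ascent_start, dv$ascent_end)

    pk <- peak_jerk_deltas(kin, orient$roll, frate,
                           c(dv$bottom_start, dv$bottom_end))
    row$bottom_peak_jerk <- pk$peak_jerk
    row$bottom_speed_change <- pk$speed_change
    row$bottom_fluke_rate_change <- pk$fluke_rate_change
    row$roll_at_peak_jerk <- pk$roll_at_peak

    start_utc <- start_time_utc + dv$t_start
    row$start_time_utc <- start_utc
    row$tod <- encode_time_of_day(start_utc)
    lt <- as.POSIXlt(start_utc, tz = "UTC")
    row$tod_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) {
    dl <- labels[labels$scope == "dive", c("dive_id", "label", "coverage")]
    out <- merge(out, dl, by = "dive_id", all.x = TRUE, sort = TRUE)
  }
  out
}
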