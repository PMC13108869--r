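# Fluke-stroke detection from the band-passed pitch-axis gyroscope, stroke
# frequency/rate statistics, and the depth-strata mixed model for the
# shallow/deep gait switch.

#' Detect fluke strokes from the band-passed pitch-axis gyroscope
#'
#' The gyroscope measures rotation rate, which leads body pitch by a
#' quarter cycle, so upward zero-crossings (sign change - to +) of the
#' band-passed y-axis signal mark the start/peak of each fluke stroke.
#' Crossing times are refined by linear interpolation between samples. An
#' amplitude gate suppresses noise-only crossings: a stroke is kept only if
#' the absolute signal within its cycle reaches `min_amplitude`.
#'
#' @param gyro_y_band band-passed (0.08-0.2 Hz) y-axis rotation rate, deg/s.
#' @param fs sampling rate, Hz.
#' @param t optional time stamps; defaults to `(0:(n-1))/fs`.
#' @param depth optional concurrent depth series (m) to annotate each peak.
#' @param min_amplitude amplitude gate, deg/s.
#' @param max_highband_fraction warn if more than this fraction of signal
#'   energy lies above 0.3 Hz (input looks unfiltered).
#' @return data.frame of class `fluke_strokes`: `peak_t` (s), `depth` (m),
#'   `interval` (s, preceding inter-peak interval; `NA` for the first
#'   stroke) and `freq` (Hz, reciprocal of the preceding interval).
#' @export
detect_fluke_strokes <- function(gyro_y_band, fs, t = NULL, depth = NULL,
                                 min_amplitude = 5,
                                 max_highband_fraction = 0.3) {
  x <- as.numeric(gyro_y_band)
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs

  if (n > 16) {
    spec <- Mod(stats::fft(x - mean(x)))^2
    freqs <- (seq_len(n) - 1) * fs / n
    half <- freqs <= fs / 2
    hi <- sum(spec[half & freqs > 0.3])
    tot <- sum(spec[half])
    if (tot > 0 && hi / tot > max_highband_fraction)
      warning("more than ", round(100 * max_highband_fraction),
              "% of signal energy above 0.3 Hz: input may not be ",
              "band-pass filtered", call. = FALSE)
  }

  up <- which(x[-n] < 0 & x[-1] >= 0)
  if (length(up) == 0) return(empty_stroke_set())
  # linear interpolation of the crossing time
  frac <- -x[up] / (x[up + 1] - x[up])
  peak_t <- t[up] + frac / fs

  # amplitude gate per cycle (crossing to next crossing, last cycle to end)
  cyc_end <- c(up[-1], n)
  keep <- vapply(seq_along(up), function(i)
    max(abs(x[up[i]:cyc_end[i]])) >= min_amplitude, logical(1))
  peak_t <- peak_t[keep]
  up <- up[keep]
  if (length(peak_t) == 0) return(empty_stroke_set())

  d <- if (is.null(depth)) rep(NA_real_, length(peak_t))
       else stats::approx(t, depth, xout = peak_t, rule = 2)$y
  interval <- c(NA, diff(peak_t))
  structure(data.frame(peak_t = peak_t, depth = d, interval = interval,
                       freq = 1 / interval),
            class = c("fluke_strokes", "data.frame"))
}

empty_stroke_set <- function() {
  structure(data.frame(peak_t = numeric(0), depth = numeric(0),
                       interval = numeric(0), freq = numeric(0)),
            class = c("fluke_strokes", "data.frame"))
}

#' Fluke-stroke frequency over a window
#'
#' Estimated as the reciprocal of the mean time between stroke peaks within
#' the window. Undefined (`NA`) with fewer than two peaks.
#'
#' @param strokes a stroke set from [detect_fluke_strokes()] (or anything
#'   with a `peak_t` column).
#' @param window optional `c(start, end)` in seconds; default all strokes.
#' @return frequency in Hz, or `NA`.
#' @export
stroke_frequency <- function(strokes, window = NULL) {
  pt <- strokes$peak_t
  if (!is.null(window)) pt <- pt[pt >= window[1] & pt <= window[2]]
  if (length(pt) < 2) return(NA_real_)
  1 / mean(diff(pt))
}

#' Rolling fluke rate
#'
#' Number of stroke peaks within a centred 30-second window evaluated at
#' each grid time.
#'
#' @param strokes stroke set (uses `peak_t`).
#' @param t_grid evaluation times, seconds.
#' @param window_s window length, seconds.
#' @return integer counts per window, same length as `t_grid`.
#' @export
rolling_fluke_rate <- function(strokes, t_grid, window_s = 30) {
  pt <- sort(strokes$peak_t)
  half <- window_s / 2
  lo <- findInterval(t_grid - half, pt, left.open = TRUE)
  hi <- findInterval(t_grid + half, pt)
  hi - lo
}

#' Pool stroke sets across deployments into a model-ready table
#'
#' @param ... named `fluke_strokes` objects (names become deployment ids),
#'   or a single named list of them.
#' @param start_time_utc named list/vector of deployment start times used to
#'   derive each stroke's UTC hour; defaults to hour 12 for all.
#' @return data.frame with `deployment_id, peak_t, depth, freq, hour`.
#' @export
pool_strokes <- function(..., start_time_utc = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "data.frame")) sets <- sets[[1]]
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("dep", seq_along(sets))
  out <- do.call(rbind, lapply(names(sets), function(id) {
    s <- sets[[id]]
    t0 <- if (!is.null(start_time_utc) && !is.null(start_time_utc[[id]]))
      as.POSIXct(start_time_utc[[id]], tz = "UTC")
    else as.POSIXct("2023-08-05 12:00:00", tz = "UTC")
    hr <- as.integer(format(t0 + s$peak_t, "%H", tz = "UTC"))
    data.frame(deployment_id = id, peak_t = s$peak_t, depth = s$depth,
               freq = s$freq, hour = hr)
  }))
  out[!is.na(out$freq), , drop = FALSE]
}

#' Depth-strata mixed model on standardized fluke-stroke frequency
#'
#' Tests the shallow/deep gait switch: per-stroke frequencies (reciprocal of
#' the preceding inter-peak interval) are z-standardized within deployment
#' (absorbing between-individual differences), outliers at |z| > 3 removed,
#' and a linear mixed model fitted with the depth stratum (shallow: depth at
#' peak <= `split_depth`; deep: > `split_depth`) as fixed effect and the
#' integer UTC hour of day as a random intercept.
#'
#' @param strokes pooled stroke table from [pool_strokes()] (columns
#'   `deployment_id, depth, freq, hour`).
#' @param split_depth stratum boundary, m (default 23).
#' @return list of class `strata_fit`: `estimate` (deep-vs-shallow effect on
#'   the standardized scale), `se`, `p_value`, `medians_hz` (named raw-scale
#'   medians), `n_strokes` (per stratum, after outlier removal), `model`.
#' @export
depth_strata_model <- function(strokes, split_depth = 23) {
  d <- strokes[!is.na(strokes$freq) & !is.na(strokes$depth), , drop = FALSE]
  sds <- tapply(d$freq, d$deployment_id, stats::sd)
  if (any(is.na(sds) | sds == 0))
    stop("cannot standardize: a deployment has fewer than 2 strokes or ",
         "zero frequency variance", call. = FALSE)
  mu <- tapply(d$freq, d$deployment_id, mean)
  d$z <- (d$freq - mu[d$deployment_id]) / sds[d$deployment_id]
  d <- d[abs(d$z) <= 3, , drop = FALSE]
  d$stratum <- factor(ifelse(d$depth <= split_depth, "shallow", "deep"),
                      levels = c("shallow", "deep"))
  if (any(table(d$stratum) == 0))
    stop("empty depth stratum at split ", split_depth, " m", call. = FALSE)
  d$hour <- factor(d$hour)

  fit <- lmerTest::lmer(z ~ stratum + (1 | hour), data = d,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  cf <- stats::coef(summary(fit))
  structure(list(
    estimate = cf["stratumdeep", "Estimate"],
    se = cf["stratumdeep", "Std. Error"],
    p_value = cf["stratumdeep", "Pr(>|t|)"],
    medians_hz = tapply(d$freq, d$stratum, stats::median),
    n_strokes = table(d$stratum),
    split_depth = split_depth,
    model = fit), class = "strata_fit")
}

#' @export
print.strata_fit <- function(x, ...) {
  cat(sprintf("Depth-strata fluke-frequency model (split %g m)\n",
              x$split_depth))
  cat(sprintf("  deep vs shallow: %.3f (SE %.3f, p = %.3g)\n",
              x$estimate, x$se, x$p_value))
  cat(sprintf("  medians: shallow %.3f Hz (n=%d), deep %.3f Hz (n=%d)\n",
              x$medians_hz[["shallow"]], x$n_strokes[["shallow"]],
              x$medians_hz[["deep"]], x$n_strokes[["deep"]]))
  invisible(x)
}
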