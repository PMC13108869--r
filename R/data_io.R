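# Central time-series container ("diary") for tag deployments:
# tri-axial accelerometer (g, whale frame: x surge/forward, y sway/left,
# z heave/up, right-handed), tri-axial gyroscope (deg/s), tri-axial
# magnetometer (arbitrary consistent units) and depth (m, positive down),
# all on one uniform time grid.

DIARY_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz",
                    "mx", "my", "mz", "depth")

#' Construct a diary series
#'
#' A `diary_series` holds the time-aligned multi-sensor record of one tag
#' deployment on a uniform time grid. Acceleration is in g (whale frame:
#' x forward, y left, z up; a level whale at rest reads `(0, 0, -1)` g),
#' rotation rate in degrees/s, depth in metres positive down.
#'
#' @param data data.frame with column `t` (seconds since deployment start)
#'   and the sensor columns `ax,ay,az,gx,gy,gz,mx,my,mz,depth`.
#' @param fs sampling rate in Hz.
#' @param deployment_id deployment identifier.
#' @param start_time_utc POSIXct timestamp of `t = 0`.
#' @return object of class `diary_series`.
#' @export
diary_series <- function(data, fs, deployment_id = "unknown",
                         start_time_utc = as.POSIXct("2023-08-05 12:00:00",
                                                     tz = "UTC")) {
  stopifnot(is.data.frame(data), is.numeric(fs), fs > 0)
  missing_cols <- setdiff(c("t", DIARY_CHANNELS), names(data))
  if (length(missing_cols) > 0)
    stop("diary is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(data) >= 2) {
    dt <- diff(data$t)
    if (any(dt <= 0))
      stop("diary time must be strictly increasing", call. = FALSE)
  }
  if (any(data$depth < -0.5))
    stop("depth below -0.5 m: depth must be positive-down metres",
         call. = FALSE)
  structure(
    list(data = data[, c("t", DIARY_CHANNELS)],
         fs = fs,
         deployment_id = deployment_id,
         start_time_utc = start_time_utc),
    class = "diary_series")
}

#' @export
print.diary_series <- function(x, ...) {
  cat(sprintf("<diary_series> %s: %d samples at %g Hz (%.1f min)\n",
              x$deployment_id, nrow(x$data), x$fs,
              nrow(x$data) / x$fs / 60))
  cat(sprintf("  start %s UTC, depth range %.1f-%.1f m\n",
              format(x$start_time_utc, "%Y-%m-%d %H:%M:%S"),
              min(x$data$depth), max(x$data$depth)))
  invisible(x)
}

#' Read a tag diary from CSV
#'
#' Expects headered CSV with an ISO-8601 `timestamp` column plus the named
#' sensor columns (see [diary_series()]). The sampling rate is inferred from
#' the timestamps unless supplied. Rows outside the optional attachment
#' window (the period the tag was actually on the animal) are dropped;
#' records before attachment or after release are non-biological.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping required names
#'   (`timestamp`, `ax`, ... `depth`) to the file's column names; defaults to
#'   identity.
#' @param deployment_id identifier; defaults to the file name.
#' @param fs sampling rate in Hz; inferred from timestamps when `NULL`.
#' @param attach_start,attach_end attachment window, POSIXct (or anything
#'   coercible); rows outside are dropped.
#' @return a [diary_series()].
#' @export
read_diary <- function(path, schema = NULL, deployment_id = NULL,
                       fs = NULL, attach_start = NULL, attach_end = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", DIARY_CHANNELS)
  if (is.null(schema)) {
    schema <- stats::setNames(required, required)
  } else {
    missing_map <- setdiff(required, names(schema))
    schema <- c(schema, stats::setNames(missing_map, missing_map))
  }
  absent <- required[!(schema[required] %in% names(raw))]
  if (length(absent) > 0)
    stop("diary file is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  ts <- as.POSIXct(raw[[schema[["timestamp"]]]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts))
    stop("unparseable timestamps in diary file", call. = FALSE)
  if (any(diff(as.numeric(ts)) <= 0))
    stop("diary timestamps are not strictly increasing", call. = FALSE)

  keep <- rep(TRUE, length(ts))
  if (!is.null(attach_start))
    keep <- keep & ts >= as.POSIXct(attach_start, tz = "UTC")
  if (!is.null(attach_end))
    keep <- keep & ts <= as.POSIXct(attach_end, tz = "UTC")
  if (!any(keep))
    stop("no diary rows inside the attachment window", call. = FALSE)
  raw <- raw[keep, , drop = FALSE]
  ts <- ts[keep]

  tsec <- as.numeric(ts) - as.numeric(ts[1])
  if (is.null(fs)) {
    if (length(tsec) < 2)
      stop("cannot infer sampling rate from a single row", call. = FALSE)
    dt <- diff(tsec)
    if ((max(dt) - min(dt)) / stats::median(dt) > 0.10)
      stop("sampling-interval jitter exceeds 10%: cannot infer fs ",
           "(gaps are not interpolated)", call. = FALSE)
    fs <- 1 / stats::median(dt)
    # snap to a round rate when within 1%
    if (abs(fs - round(fs)) / fs < 0.01) fs <- round(fs)
  }

  dat <- data.frame(t = tsec)
  for (ch in DIARY_CHANNELS) dat[[ch]] <- as.numeric(raw[[schema[[ch]]]])
  if (is.null(deployment_id))
    deployment_id <- sub("\\.csv$", "", basename(path))
  diary_series(dat, fs = fs, deployment_id = deployment_id,
               start_time_utc = ts[1])
}

#' Write a diary series to CSV
#'
#' Inverse of [read_diary()]: emits the documented headered-CSV dialect with
#' an ISO-8601 `timestamp` column.
#'
#' @param series a [diary_series()].
#' @param path output file.
#' @export
write_diary <- function(series, path) {
  stopifnot(inherits(series, "diary_series"))
  out <- series$data
  # %OS truncates rather than rounds fractional seconds; nudge by half the
  # printed resolution so 0.1-s grids survive the round trip
  ts <- series$start_time_utc + out$t + 5e-5
  out <- cbind(timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS4", tz = "UTC"),
               out[, DIARY_CHANNELS])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behaviour-event log
#'
#' Video-audit events exported as CSV with columns
#' `deployment_id,label,start_s,end_s` (times in seconds on the diary clock).
#' Labels are restricted to the closed vocabulary `Feeding`,
#' `PotentialForaging`, `Travel`.
#'
#' @param path CSV file path.
#' @return data.frame of validated events.
#' @export
read_behavior_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_behavior_events(ev)
}

#' @rdname read_behavior_events
#' @param events data.frame with columns `deployment_id,label,start_s,end_s`.
#' @export
validate_behavior_events <- function(events) {
  need <- c("deployment_id", "label", "start_s", "end_s")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0)
    stop("event log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- c("Feeding", "PotentialForaging", "Travel")
  bad <- setdiff(unique(events$label), ok)
  if (length(bad) > 0)
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ok, collapse = ", "), call. = FALSE)
  if (any(events$start_s >= events$end_s))
    stop("behaviour events must have start_s < end_s", call. = FALSE)
  events
}

#' Downsample a diary series
#'
#' Anti-alias low-pass filters every channel (zero-phase Butterworth at 80%
#' of the target Nyquist) then decimates to the target rate. Upsampling is
#' not supported. Working analyses run at 10 Hz; only the tag-jiggle speed
#' proxy uses the native rate.
#'
#' @param series a [diary_series()].
#' @param target_fs target rate in Hz; must divide the native rate.
#' @return a [diary_series()] at `target_fs`.
#' @export
resample_diary <- function(series, target_fs) {
  stopifnot(inherits(series, "diary_series"))
  if (target_fs > series$fs)
    stop("upsampling is not supported (native ", series$fs, " Hz < target ",
         target_fs, " Hz)", call. = FALSE)
  if (target_fs == series$fs) return(series)
  factor <- series$fs / target_fs
  if (abs(factor - round(factor)) > 1e-8)
    stop("native rate must be an integer multiple of the target rate",
         call. = FALSE)
  factor <- round(factor)
  cutoff <- 0.8 * target_fs / 2
  bf <- signal::butter(4, cutoff / (series$fs / 2), type = "low")
  idx <- seq(1, nrow(series$data), by = factor)
  dat <- data.frame(t = (seq_along(idx) - 1) / target_fs)
  pad <- round(10 * series$fs / cutoff)
  for (ch in DIARY_CHANNELS) {
    dat[[ch]] <- filtfilt_refl(bf, series$data[[ch]], pad)[idx]
  }
  diary_series(dat, fs = target_fs, deployment_id = series$deployment_id,
               start_time_utc = series$start_time_utc)
}
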