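# Rule-based dive detection, descent/bottom/ascent segmentation, and
# V/U/Square shape classification from the depth channel.

#' Dive-detection rules
#'
#' A dive is a depth excursion deeper than 5 m lasting at least 10 s, ended
#' by a post-dive surface interval longer than 10 s. Excursions separated by
#' a shorter surface interval belong to the same dive. "Surface" for the
#' surface-interval rule is depth shallower than 1 m.
#'
#' @param depth_threshold dive depth threshold, m.
#' @param min_duration_s minimum dive duration, s.
#' @param min_surface_s minimum post-dive surface interval, s.
#' @param surface_depth depth defining "at the surface", m.
#' @export
dive_rules <- function(depth_threshold = 5, min_duration_s = 10,
                       min_surface_s = 10, surface_depth = 1) {
  list(depth_threshold = depth_threshold, min_duration_s = min_duration_s,
       min_surface_s = min_surface_s, surface_depth = surface_depth)
}

#' Detect dives in a depth series
#'
#' Finds maximal intervals with depth above the threshold, merges
#' consecutive excursions whose intervening surface time does not exceed the
#' minimum surface interval, and drops merged excursions shorter than the
#' minimum duration. Dive start/end are clipped at the threshold crossings
#' (first/last sample beyond the threshold).
#'
#' @param depth numeric depth series, m positive down, uniformly sampled.
#' @param fs sampling rate, Hz.
#' @param t optional time stamps (seconds); defaults to `(0:(n-1))/fs`.
#' @param rules a [dive_rules()] list.
#' @return data.frame with one row per dive: `dive_id`, `t_start`, `t_end`,
#'   `max_depth` (m), `duration_min` (minutes); phase columns unset.
#' @export
detect_dives <- function(depth, fs, t = NULL, rules = dive_rules()) {
  n <- length(depth)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) stop("t and depth lengths differ", call. = FALSE)
  dt <- diff(t)
  if (n > 2 && (max(dt) - min(dt)) > 0.01 / fs)
    stop("depth series is not uniformly sampled", call. = FALSE)

  below <- depth > rules$depth_threshold
  if (!any(below)) return(empty_dive_table())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge excursions whose gap contains <= min_surface_s of true surface time
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      gap_idx <- (merged$end[nrow(merged)] + 1):(seg$start[i] - 1)
      surface_time <- sum(depth[gap_idx] < rules$surface_depth) / fs
      if (surface_time <= rules$min_surface_s) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }

  dur <- (merged$end - merged$start) / fs
  merged <- merged[dur >= rules$min_duration_s, , drop = FALSE]
  if (nrow(merged) == 0) return(empty_dive_table())

  out <- data.frame(
    dive_id = seq_len(nrow(merged)),
    t_start = t[merged$start],
    t_end = t[merged$end],
    max_depth = vapply(seq_len(nrow(merged)), function(i)
      max(depth[merged$start[i]:merged$end[i]]), numeric(1)))
  out$duration_min <- (out$t_end - out$t_start) / 60
  out
}

empty_dive_table <- function() {
  data.frame(dive_id = integer(0), t_start = numeric(0), t_end = numeric(0),
             max_depth = numeric(0), duration_min = numeric(0))
}

#' Segment a dive into descent, bottom and ascent phases
#'
#' The bottom phase is the span from the first to the last time depth
#' reaches `bottom_coef` times the dive's maximum depth (a reproducible
#' stand-in for manual bottom-phase picking; supply `manual_bottom` to
#' override). The descent runs from the first 3 m crossing (clipped to the
#' dive interval) to the bottom start; the ascent from the bottom end to the
#' last 3 m crossing. A phase of non-positive duration is recorded absent
#' (`NA`), which happens for shallow dives with no clear plateau.
#'
#' @param dives dive table from [detect_dives()].
#' @param depth,fs,t depth series as in [detect_dives()].
#' @param bottom_coef bottom-phase depth fraction of max depth.
#' @param phase_depth descent/ascent boundary depth, m.
#' @param manual_bottom optional data.frame `dive_id,t_start,t_end` of
#'   manually picked bottom phases; must lie within the dive.
#' @return dive table with phase boundary/duration columns,
#'   `bottom_fraction` and `shape` (see [classify_shape()]).
#' @export
segment_phases <- function(dives, depth, fs, t = NULL, bottom_coef = 0.8,
                           phase_depth = 3, manual_bottom = NULL) {
  n <- length(depth)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  cols <- c("descent_start", "descent_end", "bottom_start", "bottom_end",
            "ascent_start", "ascent_end")
  for (cc in cols) dives[[cc]] <- NA_real_

  for (i in seq_len(nrow(dives))) {
    in_dive <- which(t >= dives$t_start[i] & t <= dives$t_end[i])
    d <- depth[in_dive]
    td <- t[in_dive]

    if (!is.null(manual_bottom) && dives$dive_id[i] %in% manual_bottom$dive_id) {
      mb <- manual_bottom[manual_bottom$dive_id == dives$dive_id[i], ]
      if (mb$t_start[1] < dives$t_start[i] || mb$t_end[1] > dives$t_end[i])
        stop("manual bottom interval outside dive ", dives$dive_id[i],
             call. = FALSE)
      b_start <- mb$t_start[1]; b_end <- mb$t_end[1]
    } else {
      thr <- bottom_coef * max(d)
      at_bottom <- which(d >= thr)
      b_start <- td[min(at_bottom)]; b_end <- td[max(at_bottom)]
    }
    dives$bottom_start[i] <- b_start
    dives$bottom_end[i] <- b_end

    # descent: first crossing of phase_depth (clipped to the dive) -> bottom
    desc_candidates <- td[d >= phase_depth & td < b_start]
    if (length(desc_candidates) > 0 && min(desc_candidates) < b_start) {
      dives$descent_start[i] <- min(desc_candidates)
      dives$descent_end[i] <- b_start
    }
    asc_candidates <- td[d >= phase_depth & td > b_end]
    if (length(asc_candidates) > 0 && max(asc_candidates) > b_end) {
      dives$ascent_start[i] <- b_end
      dives$ascent_end[i] <- max(asc_candidates)
    }
  }
  dives$descent_min <- (dives$descent_end - dives$descent_start) / 60
  dives$bottom_min <- (dives$bottom_end - dives$bottom_start) / 60
  dives$ascent_min <- (dives$ascent_end - dives$ascent_start) / 60
  dives$bottom_fraction <- dives$bottom_min / dives$duration_min
  dives$shape <- classify_shape(dives$bottom_fraction)
  dives
}

#' Classify dive shape from bottom-time fraction
#'
#' V-shaped: bottom time is 20% or less of the dive duration. U-shaped:
#' between 20% and 50%. Square: 50% or more. The boundary at exactly 50%
#' goes to Square so that ties are deterministic.
#'
#' @param bottom_fraction numeric in `[0, 1]`: bottom duration / dive
#'   duration.
#' @return character vector of `"V"`, `"U"` or `"Square"`.
#' @export
classify_shape <- function(bottom_fraction) {
  if (any(is.na(bottom_fraction)))
    stop("cannot classify shape: missing bottom phase", call. = FALSE)
  ifelse(bottom_fraction <= 0.20, "V",
         ifelse(bottom_fraction < 0.50, "U", "Square"))
}

#' Summarise dive shapes
#'
#' Counts and percentages per shape class, optionally split by a grouping
#' factor (e.g. behaviour label).
#'
#' @param shape character vector of shape classes (or a dive table with a
#'   `shape` column).
#' @return data.frame with `shape`, `n`, `pct`.
#' @export
dive_shape_summary <- function(shape) {
  if (is.data.frame(shape)) shape <- shape$shape
  tab <- table(factor(shape, levels = c("Square", "U", "V")))
  data.frame(shape = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(shape))
}

#' Per-deployment dive-count summary
#'
#' Totals, mean and sample standard deviation of dive counts across
#' deployments — the standard per-deployment summary row.
#'
#' @param counts integer vector of dives per deployment.
#' @return list with `total`, `mean`, `sd`, `n_deployments`.
#' @export
dive_count_summary <- function(counts) {
  list(total = sum(counts), mean = mean(counts), sd = stats::sd(counts),
       n_deployments = length(counts))
}
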