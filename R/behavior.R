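# Hierarchical matching of video-audit behaviour events onto dives and
# dive phases.

BEHAVIOR_PRECEDENCE <- c("Feeding", "PotentialForaging", "Travel")

# overlap of each event with [t0, t1], seconds
event_overlap <- function(events, t0, t1) {
  pmax(0, pmin(events$end_s, t1) - pmax(events$start_s, t0))
}

assign_one_scope <- function(events, t0, t1) {
  if (is.na(t0) || is.na(t1) || t1 <= t0)
    return(list(label = NA_character_, coverage = NA_real_))
  ov <- event_overlap(events, t0, t1)
  hit <- events[ov > 0, , drop = FALSE]
  ov <- ov[ov > 0]
  if (nrow(hit) == 0)
    return(list(label = "NoVideo", coverage = 0))
  # union coverage of the scope by any event
  iv <- cbind(pmax(hit$start_s, t0), pmin(hit$end_s, t1))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  covered <- 0; cur_end <- -Inf
  for (i in seq_len(nrow(iv))) {
    s <- max(iv[i, 1], cur_end)
    if (iv[i, 2] > s) covered <- covered + (iv[i, 2] - s)
    cur_end <- max(cur_end, iv[i, 2])
  }
  coverage <- covered / (t1 - t0)

  by_label <- tapply(ov, hit$label, sum)
  labels <- names(by_label)
  if (length(labels) == 1) {
    lab <- labels
  } else if ("Feeding" %in% labels) {
    # Feeding takes priority regardless of time spent feeding
    lab <- "Feeding"
  } else {
    best <- by_label == max(by_label)
    cand <- labels[best]
    lab <- BEHAVIOR_PRECEDENCE[BEHAVIOR_PRECEDENCE %in% cand][1]
  }
  list(label = lab, coverage = coverage)
}

#' Assign behaviour labels to dives and dive phases
#'
#' Hierarchical assignment of audited behaviour events to each scope (whole
#' dive, descent, bottom, ascent): events overlapping the scope are
#' collected; with no overlap at all the scope is `NoVideo`; a single
#' observed behaviour is assigned directly; with several behaviours,
#' `Feeding` always wins regardless of duration; otherwise the behaviour
#' with the longest overlapped duration wins, ties broken by the precedence
#' Feeding > PotentialForaging > Travel. Identically labelled overlapping
#' events merge naturally (durations are unioned for coverage, summed per
#' label for dominance).
#'
#' @param dives segmented dive table (needs `dive_id`, `t_start`, `t_end`
#'   and, when present, phase boundary columns from [segment_phases()]).
#' @param events behaviour-event data.frame
#'   (`deployment_id,label,start_s,end_s`, diary clock); see
#'   [read_behavior_events()].
#' @return data.frame with one row per (dive, scope): `dive_id`, `scope`
#'   (`dive`/`descent`/`bottom`/`ascent`), `label`, `coverage` (fraction of
#'   the scope overlapped by any event). Scopes for absent phases are `NA`.
#' @export
assign_behavior <- function(dives, events) {
  events <- validate_behavior_events(events)
  scopes <- list(
    dive = c("t_start", "t_end"),
    descent = c("descent_start", "descent_end"),
    bottom = c("bottom_start", "bottom_end"),
    ascent = c("ascent_start", "ascent_end"))
  out <- do.call(rbind, lapply(seq_len(nrow(dives)), function(i) {
    do.call(rbind, lapply(names(scopes), function(sc) {
      cols <- scopes[[sc]]
      t0 <- if (cols[1] %in% names(dives)) dives[[cols[1]]][i] else NA
      t1 <- if (cols[2] %in% names(dives)) dives[[cols[2]]][i] else NA
      a <- assign_one_scope(events, t0, t1)
      data.frame(dive_id = dives$dive_id[i], scope = sc,
                 label = a$label, coverage = a$coverage)
    }))
  }))
  rownames(out) <- NULL
  out
}
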