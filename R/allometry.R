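# Small physical/biological helpers.

#' Wave-drag cessation depth
#'
#' Wave drag on a submerged swimmer decays with depth and becomes
#' negligible below roughly three body diameters. For a whale of girth
#' (diameter) `girth_m` metres the cessation depth is `3 * girth_m`:
#' a 4.8 m-girth animal escapes wave drag below 14.4 m.
#'
#' @param girth_m body girth (diameter), metres.
#' @param multiple depth multiple at which wave drag ceases (default 3).
#' @return depth in metres.
#' @export
wave_drag_cessation_depth <- function(girth_m, multiple = 3) {
  stopifnot(girth_m > 0)
  multiple * girth_m
}
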