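# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# diary with constant channels (level whale at rest)
make_toy_diary <- function(n = 100, fs = 10, depth = 0) {
  diary_series(
    data.frame(t = (seq_len(n) - 1) / fs,
               ax = 0, ay = 0, az = -1,
               gx = 0, gy = 0, gz = 0,
               mx = 1, my = 0, mz = 0,
               depth = depth),
    fs = fs, deployment_id = "toy")
}

# piecewise-linear depth trace from (duration_s, depth_target) breakpoints;
# starts at depth 0, linear ramps between targets
make_depth_trace <- function(segments, fs = 1) {
  depth <- 0
  cur <- 0
  for (i in seq_len(nrow(segments))) {
    ns <- round(segments$dur[i] * fs)
    depth <- c(depth, cur + (segments$depth[i] - cur) * seq_len(ns) / ns)
    cur <- segments$depth[i]
  }
  depth
}

# symmetric trapezoid dive: surface, linear descent, flat bottom, linear
# ascent, surface
trapezoid_depth <- function(fs = 1, surface_s = 60, descent_s = 30,
                            bottom_s = 60, ascent_s = 30, depth = 20) {
  make_depth_trace(data.frame(
    dur = c(surface_s, descent_s, bottom_s, ascent_s, surface_s),
    depth = c(0, depth, depth, 0, 0)), fs = fs)
}

# behaviour event rows
ev <- function(label, start, end, id = "d1") {
  data.frame(deployment_id = id, label = label, start_s = start, end_s = end)
}
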