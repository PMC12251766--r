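# Independent oracles and fixture builders shared across the suite.

# Brute-force run-length-merge oracle for event segmentation.
# `activity` is a logical vector (TRUE = some beam interrupted that frame).
# Returns a data.frame of 0-based inclusive start/end frames of events,
# computed by grouping active positions whose spacing is <= gap + 1 and
# keeping groups with at least `min_active` members.
oracle_segment <- function(activity, gap = 5, min_active = 2) {
  pos <- which(activity)
  if (length(pos) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  group <- cumsum(c(1, diff(pos) > gap + 1))
  out <- do.call(rbind, lapply(split(pos, group), function(p) {
    if (length(p) < min_active) return(NULL)
    data.frame(start = p[1] - 1L, end = p[length(p)] - 1L)
  }))
  if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

# Build a stream whose bottom beam of array A is interrupted exactly at the
# active frames; everything else intact.
stream_from_activity <- function(activity, config = mini_config()) {
  n <- length(activity)
  a <- matrix(1L, n, config$n_beams)
  b <- matrix(1L, n, config$n_beams)
  a[activity, 1] <- 0L
  beam_stream(config, a, b)
}

# Build a candidate event directly from crafted state matrices.
candidate_from_states <- function(states_a, states_b,
                                  config = mini_config(),
                                  start_frame = 0L) {
  n <- nrow(states_a)
  stream <- beam_stream(config, states_a, states_b)
  ev <- candidate_event(stream, 0L, n - 1L)
  ev$start_frame <- as.integer(start_frame)
  ev$end_frame <- as.integer(start_frame + n - 1L)
  ev
}

# Intact matrix of the given size.
intact <- function(n_frames, config = mini_config()) {
  matrix(1L, n_frames, config$n_beams)
}

# Sharp bounds on the height estimate for a rigid body of height h at beam
# pitch s with additive correction c: the closed body interval intersects
# floor(h/s) or floor(h/s) + 1 beam lines depending on vertical offset, so
# the estimate is (m - 1) * s + c for m in that set.
height_estimate_set <- function(h, s, corr) {
  m <- floor(h / s + 1e-9)
  c((m - 1) * s + corr, m * s + corr)
}

# Default replica fish used throughout: larger dummy geometry.
dummy_fish <- function(...) {
  fish_spec(length = 16.5, height = 6.4, depth_center = 29.25, speed = 30, ...)
}

run_pipeline <- function(stream, ...) classify_stream(stream, ...)
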