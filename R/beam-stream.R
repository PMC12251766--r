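#' Beam-state stream
#'
#' A time-ordered sequence of curtain frames. Each frame records the binary
#' state of every beam in both arrays at one sample instant: 0 = interrupted,
#' 1 = intact. States are stored as two integer matrices with one row per
#' frame and one column per beam (column 1 = bottom beam). Row i corresponds
#' to frame index i - 1; the wall-clock time of frame k is
#' `start_time + k / sampling_rate`.
#'
#' @param config A [sensor_config()].
#' @param states_a,states_b Integer 0/1 matrices, frames x beams, for arrays
#'   A and B. Must have identical dimensions and `n_beams` columns.
#' @param start_time POSIXct wall-clock time of frame 0. Defaults to the Unix
#'   epoch in UTC.
#' @return An object of class `beam_stream`.
#' @export
beam_stream <- function(config, states_a, states_b,
                        start_time = as.POSIXct("1970-01-01", tz = "UTC")) {
  stopifnot(inherits(config, "sensor_config"))
  states_a <- as_state_matrix(states_a, config$n_beams)
  states_b <- as_state_matrix(states_b, config$n_beams)
  if (!identical(dim(states_a), dim(states_b))) {
    stop("states_a and states_b must have identical dimensions")
  }
  stopifnot(inherits(start_time, "POSIXct"), length(start_time) == 1)
  structure(
    list(
      config = config,
      start_time = start_time,
      states_a = states_a,
      states_b = states_b
    ),
    class = "beam_stream"
  )
}

as_state_matrix <- function(x, n_beams) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    x <- matrix(integer(0), nrow = 0, ncol = n_beams)
  }
  if (ncol(x) != n_beams) {
    stop(sprintf("state matrix has %d columns; config expects %d beams",
                 ncol(x), n_beams))
  }
  storage.mode(x) <- "integer"
  if (length(x) && !all(x %in% c(0L, 1L))) {
    stop("beam states must be 0 (interrupted) or 1 (intact)")
  }
  dimnames(x) <- NULL
  x
}

#' @export
print.beam_stream <- function(x, ...) {
  n <- n_frames(x)
  dur <- n / x$config$sampling_rate
  cat(sprintf(
    "<beam_stream> %d frames (%.2f s at %g Hz), %d beams/array, start %s\n",
    n, dur, x$config$sampling_rate, x$config$n_beams,
    format_iso8601(x$start_time)
  ))
  n_int <- sum(x$states_a == 0L) + sum(x$states_b == 0L)
  cat(sprintf("  %d interrupted beam-samples (%d frames active)\n",
              n_int, sum(active_frames(x))))
  invisible(x)
}

#' Number of frames in a stream
#' @param stream A [beam_stream()].
#' @return Integer frame count.
#' @export
n_frames <- function(stream) {
  nrow(stream$states_a)
}

#' Wall-clock times of every frame
#' @param stream A [beam_stream()].
#' @return POSIXct vector, one element per frame.
#' @export
frame_times <- function(stream) {
  stream$start_time +
    (seq_len(n_frames(stream)) - 1) / stream$config$sampling_rate
}

# Logical vector: TRUE where any beam of either array is interrupted.
active_frames <- function(stream) {
  if (n_frames(stream) == 0) return(logical(0))
  rowSums(stream$states_a == 0L) + rowSums(stream$states_b == 0L) > 0
}

#' Reverse a stream in time
#'
#' Returns the stream with its frame order reversed, keeping the same start
#' time. Useful for symmetry checks: a time-reversed passage travels in the
#' opposite direction with identical geometry.
#'
#' @param stream A [beam_stream()].
#' @return A `beam_stream`.
#' @export
reverse_stream <- function(stream) {
  idx <- rev(seq_len(n_frames(stream)))
  beam_stream(stream$config,
              stream$states_a[idx, , drop = FALSE],
              stream$states_b[idx, , drop = FALSE],
              start_time = stream$start_time)
}

format_iso8601 <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS3%z", tz = attr(t, "tzone") %||% "UTC")
}

parse_iso8601 <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  if (is.na(t)) stop(sprintf("cannot parse timestamp '%s'", s))
  t
}

`%||%` <- function(a, b) if (is.null(a)) b else a
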