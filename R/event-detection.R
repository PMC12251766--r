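#' Candidate passage event
#'
#' A contiguous slice of a beam stream hypothesised to contain one fish
#' passage. Frame indices are 0-based positions in the source stream; the
#' first and last frame of the slice always contain at least one interrupted
#' beam.
#'
#' @param stream Source [beam_stream()].
#' @param start_frame,end_frame Inclusive 0-based frame indices of the slice.
#' @param provenance Optional source log identifier.
#' @return An object of class `candidate_event`.
#' @export
candidate_event <- function(stream, start_frame, end_frame, provenance = "") {
  stopifnot(start_frame >= 0, end_frame >= start_frame,
            end_frame < n_frames(stream))
  rows <- (start_frame + 1):(end_frame + 1)
  structure(
    list(
      start_frame = as.integer(start_frame),
      end_frame = as.integer(end_frame),
      states_a = stream$states_a[rows, , drop = FALSE],
      states_b = stream$states_b[rows, , drop = FALSE],
      config = stream$config,
      stream_start_time = stream$start_time,
      provenance = provenance
    ),
    class = "candidate_event"
  )
}

#' @export
print.candidate_event <- function(x, ...) {
  cat(sprintf(
    "<candidate_event> frames %d-%d (%d frames), %d interrupted beam-samples\n",
    x$start_frame, x$end_frame, nrow(x$states_a),
    sum(x$states_a == 0L) + sum(x$states_b == 0L)
  ))
  invisible(x)
}

#' Segment a beam stream into candidate passage events
#'
#' A frame is *active* when any beam of either array is interrupted.
#' Maximal runs of active frames become candidate events; runs separated by
#' at most `gap_frames` fully-intact frames are merged (so momentary full
#' clearances inside one passage do not split it), and merged runs with
#' fewer than `min_active_frames` active frames are dropped. Candidates are
#' disjoint, ordered, and trimmed so their first and last frames are active.
#'
#' @param stream A [beam_stream()].
#' @param gap_frames Maximum run of intact frames bridged inside one event.
#' @param min_active_frames Minimum number of active frames per event.
#' @param provenance Source log identifier stored on each candidate.
#' @return List of [candidate_event()] objects (possibly empty).
#' @export
segment_events <- function(stream, gap_frames = 5L, min_active_frames = 2L,
                           provenance = "") {
  stopifnot(gap_frames >= 0, min_active_frames >= 1)
  act <- active_frames(stream)
  if (!any(act)) return(list())
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge active runs separated by short intact gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= gap_frames) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  out <- list()
  for (i in seq_len(nrow(merged))) {
    n_active <- sum(act[merged$start[i]:merged$end[i]])
    if (n_active >= min_active_frames) {
      out[[length(out) + 1L]] <- candidate_event(
        stream, merged$start[i] - 1L, merged$end[i] - 1L,
        provenance = provenance
      )
    }
  }
  out
}

#' Remove spurious beam interruptions from a candidate event
#'
#' Environmental noise shows up as short, isolated interruptions: connected
#' groups of interrupted cells (4-connected in the frame x beam grid, per
#' array) spanning at most `max_width_frames` frames and
#' `max_height_beams` beams, with no corresponding interruption on the other
#' array nearby in time. Such groups are reset to intact. Event bounds are
#' re-trimmed afterwards; an event emptied of interruptions is dropped
#' (returns `NULL`). The operation only ever removes interruptions, and is
#' idempotent.
#'
#' @param event A [candidate_event()].
#' @param max_width_frames Maximum temporal width (frames) of a removable
#'   group.
#' @param max_height_beams Maximum vertical extent (beams) of a removable
#'   group.
#' @param require_cross_array If `TRUE` (default), a group is only removed
#'   when the other array shows no *corresponding* interruption — one within
#'   `cross_tol_frames` frames and `cross_beam_tol` beams of the group — so
#'   a near-simultaneous, vertically co-located detection on both arrays is
#'   treated as a real (if small) object.
#' @param cross_tol_frames Temporal tolerance (frames) for the cross-array
#'   counterpart check; defaults to the frames a slow fish needs to transit
#'   the array gap.
#' @param cross_beam_tol Vertical tolerance (beams) for the counterpart
#'   check: a real body crosses both arrays at nearly the same height.
#' @return A cleaned `candidate_event`, or `NULL` if nothing remains.
#' @export
remove_random_lines <- function(event, max_width_frames = 2L,
                                max_height_beams = 1L,
                                require_cross_array = TRUE,
                                cross_tol_frames = 5L,
                                cross_beam_tol = 3L) {
  stopifnot(inherits(event, "candidate_event"))
  a <- event$states_a
  b <- event$states_b
  n <- nrow(a)
  clean_one <- function(this, other) {
    labels <- label_components(this == 0L)
    if (is.null(labels)) return(this)
    for (lab in seq_len(attr(labels, "n"))) {
      cells <- which(labels == lab, arr.ind = TRUE)
      width <- diff(range(cells[, 1])) + 1L
      height <- diff(range(cells[, 2])) + 1L
      if (width > max_width_frames || height > max_height_beams) next
      if (require_cross_array) {
        f0 <- max(1L, min(cells[, 1]) - cross_tol_frames)
        f1 <- min(n, max(cells[, 1]) + cross_tol_frames)
        j0 <- max(1L, min(cells[, 2]) - cross_beam_tol)
        j1 <- min(ncol(this), max(cells[, 2]) + cross_beam_tol)
        if (any(other[f0:f1, j0:j1] == 0L)) next
      }
      this[cells] <- 1L
    }
    this
  }
  a2 <- clean_one(a, b)
  b2 <- clean_one(b, a)
  act <- rowSums(a2 == 0L) + rowSums(b2 == 0L) > 0
  if (!any(act)) return(NULL)
  first <- which(act)[1]
  last <- which(act)[sum(act)]
  out <- event
  out$states_a <- a2[first:last, , drop = FALSE]
  out$states_b <- b2[first:last, , drop = FALSE]
  out$start_frame <- event$start_frame + first - 1L
  out$end_frame <- event$start_frame + last - 1L
  out
}

# Label 4-connected components of TRUE cells in a logical matrix.
# Returns an integer matrix of labels (0 = background) with attribute "n",
# or NULL when there are no TRUE cells.
label_components <- function(mask) {
  if (!any(mask)) return(NULL)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  n_lab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    n_lab <- n_lab + 1L
    queue <- start
    labels[start] <- n_lab
    while (length(queue)) {
      cell <- queue[[1]]
      queue <- queue[-1]
      i <- ((cell - 1L) %% nr) + 1L
      j <- ((cell - 1L) %/% nr) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > nc) next
        idx <- (nb[2] - 1L) * nr + nb[1]
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- n_lab
          queue <- c(queue, idx)
        }
      }
    }
  }
  attr(labels, "n") <- n_lab
  labels
}
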