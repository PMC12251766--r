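#' @name kinematics
#' @title Kinematic and morphometric estimation for candidate events
#'
#' @description
#' A passage across the two-array curtain yields two timing cues per event:
#' the delay between the *first* interruption of each array (the nose
#' entering) and the delay between the *last* interruption of each array
#' (the tail leaving). From these the pipeline derives travel direction,
#' entry/exit velocity `V = D / dt` (D = array gap), body length
#' `L = V * T` (T = per-array occupancy duration), body height from the
#' vertical extent of interrupted beams, and a 2D silhouette sampled at
#' horizontal steps `dx = V / f`.
#'
#' An array's activation is per-array: the first/last frame in which *any*
#' of its beams is interrupted. Undefined quantities (e.g. velocity when
#' the inter-array delay is zero frames) are propagated as `NA` and later
#' rejected by [filter_events()], never clamped.
NULL

# First/last active frame (1-based, relative to the event slice) per array;
# NA when the array was never interrupted.
array_activation <- function(event) {
  f <- function(states) {
    act <- rowSums(states == 0L) > 0
    if (!any(act)) return(c(first = NA_integer_, last = NA_integer_))
    w <- which(act)
    c(first = w[1], last = w[length(w)])
  }
  list(a = f(event$states_a), b = f(event$states_b))
}

#' Estimate entry and exit travel direction
#'
#' Direction is +1 for travel from array A to array B, -1 for B to A, and 0
#' when indeterminate (both arrays first hit in the same frame, or one array
#' never interrupted). The entry component compares first activations, the
#' exit component last activations (the array cleared last is on the far
#' side of travel).
#'
#' @param event A cleaned [candidate_event()].
#' @return List with integer components `entry` and `exit` in {-1, 0, +1}.
#' @export
estimate_directions <- function(event) {
  act <- array_activation(event)
  comp <- function(ta, tb) {
    if (is.na(ta) || is.na(tb)) return(0L)
    as.integer(sign(tb - ta))
  }
  list(entry = comp(act$a["first"], act$b["first"]),
       exit = comp(act$a["last"], act$b["last"]))
}

#' Estimate entry and exit swimming velocity
#'
#' `V = D / dt` with D the array gap and dt the inter-array delay of the
#' first (entry) or last (exit) activation, in seconds. A zero-frame delay
#' leaves that component undefined (`NA`); the mean is taken over the
#' defined components, `NA` when neither is defined.
#'
#' @param event A cleaned [candidate_event()].
#' @return List with numeric components `entry`, `exit`, `mean` (cm/s).
#' @export
estimate_velocities <- function(event) {
  cfg <- event$config
  act <- array_activation(event)
  comp <- function(ta, tb) {
    if (is.na(ta) || is.na(tb)) return(NA_real_)
    d_frames <- abs(unname(tb) - unname(ta))
    if (d_frames == 0) return(NA_real_)
    cfg$array_gap / (d_frames / cfg$sampling_rate)
  }
  entry <- comp(act$a["first"], act$b["first"])
  exit <- comp(act$a["last"], act$b["last"])
  defined <- c(entry, exit)[!is.na(c(entry, exit))]
  list(entry = entry, exit = exit,
       mean = if (length(defined)) mean(defined) else NA_real_)
}

#' Estimate body length from velocity and occupancy duration
#'
#' For each array X that was interrupted, the occupancy duration is
#' `T_X = (last_active - first_active) / f`; the per-array length is
#' `velocity$mean * T_X`, and the reported length is the mean over the
#' interrupted arrays.
#'
#' @param event A cleaned [candidate_event()].
#' @param velocity Result of [estimate_velocities()].
#' @return List with numeric components `length_a`, `length_b`, `length`
#'   (cm); all `NA` when the mean velocity is undefined.
#' @export
estimate_length <- function(event, velocity) {
  cfg <- event$config
  if (is.na(velocity$mean)) {
    return(list(length_a = NA_real_, length_b = NA_real_, length = NA_real_))
  }
  act <- array_activation(event)
  one <- function(fl) {
    if (is.na(fl["first"])) return(NA_real_)
    velocity$mean * (fl["last"] - fl["first"]) / cfg$sampling_rate
  }
  la <- unname(one(act$a))
  lb <- unname(one(act$b))
  defined <- c(la, lb)[!is.na(c(la, lb))]
  list(length_a = la, length_b = lb,
       length = if (length(defined)) mean(defined) else NA_real_)
}

#' Estimate body height from the vertical beam extent
#'
#' Over the union of interrupted cells in both arrays across the whole
#' event, `height = (j_max - j_min) * beam_spacing + height_correction`.
#' The correction (default half a beam pitch) compensates partial beam
#' occlusion: a single interrupted beam would otherwise read as zero
#' height.
#'
#' @param event A cleaned [candidate_event()] with at least one
#'   interruption.
#' @return Height in cm.
#' @export
estimate_height <- function(event) {
  cfg <- event$config
  hit <- (colSums(event$states_a == 0L) + colSums(event$states_b == 0L)) > 0
  if (!any(hit)) stop("event contains no interrupted beams")
  j <- which(hit)
  (max(j) - min(j)) * cfg$beam_spacing + cfg$height_correction
}

#' Reconstruct the 2D silhouette of a passage
#'
#' Maps the per-frame interrupted-beam profile of one reference array
#' (array A, falling back to B if A was never touched) against the
#' horizontal distance travelled between samples, `dx = velocity$mean / f`.
#' When the travel direction is -1 the column order is reversed so the nose
#' is always drawn first.
#'
#' @param event A cleaned [candidate_event()].
#' @param velocity Result of [estimate_velocities()]; `mean` must be
#'   defined.
#' @param direction Signed travel direction used to orient the silhouette
#'   (+1 = A-to-B). Defaults to the entry direction estimate.
#' @return List of class `silhouette` with components `dx` (cm per column),
#'   `occupancy` (binary frames x beams matrix, 1 = body present),
#'   `extent` (length, height in cm), `array` (reference array label), or
#'   `NULL` when velocity is undefined.
#' @export
reconstruct_silhouette <- function(event, velocity,
                                   direction = estimate_directions(event)$entry) {
  cfg <- event$config
  if (is.na(velocity$mean)) return(NULL)
  use_a <- any(event$states_a == 0L)
  states <- if (use_a) event$states_a else event$states_b
  act <- rowSums(states == 0L) > 0
  w <- which(act)
  occ <- (states[w[1]:w[length(w)], , drop = FALSE] == 0L) * 1L
  if (!is.na(direction) && direction < 0) {
    occ <- occ[rev(seq_len(nrow(occ))), , drop = FALSE]
  }
  dx <- velocity$mean / cfg$sampling_rate
  j <- which(colSums(occ) > 0)
  structure(
    list(
      dx = dx,
      occupancy = occ,
      extent = c(length = (nrow(occ) - 1) * dx,
                 height = (max(j) - min(j)) * cfg$beam_spacing +
                   cfg$height_correction),
      beam_spacing = cfg$beam_spacing,
      array = if (use_a) cfg$array_labels[1] else cfg$array_labels[2]
    ),
    class = "silhouette"
  )
}

#' Wall-clock timestamp of an event
#'
#' @param event A [candidate_event()].
#' @return POSIXct: stream start time + start_frame / f.
#' @export
assign_timestamp <- function(event) {
  event$stream_start_time +
    event$start_frame / event$config$sampling_rate
}

#' Plot a reconstructed silhouette
#'
#' Draws the occupancy matrix with both axes in cm: the horizontal axis is
#' distance travelled (columns spaced `dx` apart), the vertical axis beam
#' height.
#'
#' @param x A `silhouette`.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::image()].
#' @export
plot.silhouette <- function(x, main = "Reconstructed silhouette", ...) {
  xs <- (seq_len(nrow(x$occupancy)) - 1) * x$dx
  ys <- (seq_len(ncol(x$occupancy)) - 1) * x$beam_spacing
  graphics::image(
    x = xs, y = ys,
    z = x$occupancy,
    col = c("white", "grey20"),
    xlab = "distance travelled (cm)", ylab = "height (cm)",
    main = main, useRaster = TRUE, ...
  )
  invisible(x)
}
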