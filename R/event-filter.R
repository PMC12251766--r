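#' Three-criterion validity filter for candidate events
#'
#' A candidate becomes a validated passage only if, in order:
#' 1. *Directionality*: the sum of the entry and exit direction estimates is
#'    non-zero — a turnaround or indecisive event has entry and exit signs
#'    cancelling (or both indeterminate).
#' 2. *Velocity plausibility*: the mean swimming velocity is defined and
#'    strictly positive (stationary debris gives a zero inter-array delay).
#'    An optional maximum-velocity cap can be supplied.
#' 3. *Morphological coherence*: the estimated body height reaches the
#'    configured biological plausibility threshold.
#'
#' Rejected events carry the first failed criterion as their reason
#' (`"direction"`, `"velocity"`, or `"height"`). The final direction of an
#' accepted event is `sign(entry + exit)`.
#'
#' @param candidates List of cleaned [candidate_event()] objects.
#' @param max_velocity Optional upper velocity cap in cm/s (`Inf` = off).
#' @return List with components `accepted` (list of `passage_event`) and
#'   `rejected` (list of `list(event, reason)`).
#' @export
filter_events <- function(candidates, max_velocity = Inf) {
  accepted <- list()
  rejected <- list()
  for (event in candidates) {
    direction <- estimate_directions(event)
    velocity <- estimate_velocities(event)
    morpho <- estimate_length(event, velocity)
    morpho$height <- estimate_height(event)
    reason <- NULL
    if (direction$entry + direction$exit == 0L) {
      reason <- "direction"
    } else if (is.na(velocity$mean) || velocity$mean <= 0 ||
               velocity$mean > max_velocity) {
      reason <- "velocity"
    } else if (morpho$height < event$config$height_filter_threshold) {
      reason <- "height"
    }
    if (is.null(reason)) {
      final_dir <- as.integer(sign(direction$entry + direction$exit))
      accepted[[length(accepted) + 1L]] <- structure(
        list(
          candidate = event,
          direction = final_dir,
          direction_estimate = direction,
          velocity = velocity,
          morphometrics = morpho,
          silhouette = reconstruct_silhouette(event, velocity, final_dir),
          timestamp = assign_timestamp(event)
        ),
        class = "passage_event"
      )
    } else {
      rejected[[length(rejected) + 1L]] <- list(event = event, reason = reason)
    }
  }
  list(accepted = accepted, rejected = rejected)
}

#' @export
print.passage_event <- function(x, ...) {
  cat(sprintf(
    "<passage_event> %s dir %+d, V = %.1f cm/s, L = %.1f cm, H = %.2f cm\n",
    format_iso8601(x$timestamp), x$direction, x$velocity$mean,
    x$morphometrics$length, x$morphometrics$height
  ))
  invisible(x)
}

#' Run the full classification chain on a beam stream
#'
#' Segments the stream ([segment_events()]), strips spurious interruptions
#' ([remove_random_lines()]), estimates kinematics and morphometrics, and
#' applies the validity filter ([filter_events()]).
#'
#' @param stream A [beam_stream()].
#' @param gap_frames,min_active_frames Segmentation parameters, see
#'   [segment_events()].
#' @param noise_max_width,noise_max_height,require_cross_array,cross_tol_frames,cross_beam_tol
#'   Noise-removal parameters, see [remove_random_lines()].
#' @param max_velocity Optional velocity cap, see [filter_events()].
#' @param provenance Source log identifier.
#' @return List with `accepted` (passage events), `rejected`
#'   (event + reason), and `n_candidates` (count after noise cleaning).
#' @export
classify_stream <- function(stream, gap_frames = 5L, min_active_frames = 2L,
                            noise_max_width = 2L, noise_max_height = 1L,
                            require_cross_array = TRUE, cross_tol_frames = 5L,
                            cross_beam_tol = 3L,
                            max_velocity = Inf, provenance = "") {
  candidates <- segment_events(stream, gap_frames, min_active_frames,
                               provenance = provenance)
  cleaned <- list()
  for (event in candidates) {
    ev <- remove_random_lines(event, noise_max_width, noise_max_height,
                              require_cross_array, cross_tol_frames,
                              cross_beam_tol)
    if (!is.null(ev)) cleaned[[length(cleaned) + 1L]] <- ev
  }
  res <- filter_events(cleaned, max_velocity = max_velocity)
  res$n_candidates <- length(cleaned)
  res
}

#' Tabulate accepted passage events
#'
#' @param accepted List of `passage_event` objects.
#' @param config A [sensor_config()] (for direction labels).
#' @return Data.frame with one row per event: `timestamp`, `direction`,
#'   `direction_label`, `velocity`, `length`, `height`.
#' @export
events_table <- function(accepted, config) {
  if (length(accepted) == 0) {
    return(data.frame(
      timestamp = as.POSIXct(character(0), tz = "UTC"),
      direction = integer(0), direction_label = character(0),
      velocity = numeric(0), length = numeric(0), height = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(accepted, function(ev) {
    data.frame(
      timestamp = ev$timestamp,
      direction = ev$direction,
      direction_label = direction_label(ev$direction, config),
      velocity = ev$velocity$mean,
      length = ev$morphometrics$length,
      height = ev$morphometrics$height,
      stringsAsFactors = FALSE
    )
  }))
}
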