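#' Match detections against ground truth by timestamp
#'
#' Greedy one-to-one matching: detection/truth pairs are considered in order
#' of increasing time difference; each pair within `time_tol_s` whose
#' members are both still unmatched becomes a hit. Unmatched truths marked
#' detectable become misses; unmatched truths marked not detectable are
#' reported separately; unmatched detections are false positives.
#'
#' @param detections Data.frame with a POSIXct `timestamp` column (e.g. from
#'   [events_table()] or [read_event_log()]).
#' @param truth Data.frame with POSIXct `time`, logical
#'   `expected_detectable`, and `scenario_tag` columns (from the simulator).
#' @param time_tol_s Matching tolerance in seconds.
#' @return List with data.frames `hits` (detection index, truth index, time
#'   error), `misses` and `undetectable` (truth rows), and
#'   `false_positives` (detection rows).
#' @export
match_events <- function(detections, truth, time_tol_s = 2) {
  nd <- nrow(detections)
  nt <- nrow(truth)
  pairs <- expand.grid(det = seq_len(nd), tru = seq_len(nt))
  if (nrow(pairs)) {
    pairs$dt <- abs(as.numeric(detections$timestamp[pairs$det]) -
                      as.numeric(truth$time[pairs$tru]))
    pairs <- pairs[pairs$dt <= time_tol_s, , drop = FALSE]
    pairs <- pairs[order(pairs$dt), , drop = FALSE]
  }
  det_used <- rep(FALSE, nd)
  tru_used <- rep(FALSE, nt)
  hits <- pairs[0, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$det[i]; u <- pairs$tru[i]
    if (!det_used[d] && !tru_used[u]) {
      det_used[d] <- TRUE
      tru_used[u] <- TRUE
      hits <- rbind(hits, pairs[i, ])
    }
  }
  rownames(hits) <- NULL
  unmatched_truth <- truth[!tru_used, , drop = FALSE]
  list(
    hits = hits,
    misses = unmatched_truth[unmatched_truth$expected_detectable, ,
                             drop = FALSE],
    undetectable = unmatched_truth[!unmatched_truth$expected_detectable, ,
                                   drop = FALSE],
    false_positives = detections[!det_used, , drop = FALSE]
  )
}

#' Detection rate
#'
#' @param n_hits Number of true-positive detections.
#' @param n_truths Number of detectable true passages (must be >= 1).
#' @return Percentage `100 * n_hits / n_truths`.
#' @export
detection_rate <- function(n_hits, n_truths) {
  stopifnot(n_truths >= 1)
  100 * n_hits / n_truths
}

#' Categorise missed passages by error mechanism
#'
#' @param misses Data.frame of missed truth records carrying a
#'   `scenario_tag` column (tags `case_I` .. `case_IV`), or a character
#'   vector of tags.
#' @return Data.frame with columns `category`, `count`, `percentage`
#'   (percentages of total misses, summing to 100 when any miss exists);
#'   zero rows when there are no misses.
#' @export
categorize_errors <- function(misses) {
  tags <- if (is.data.frame(misses)) misses$scenario_tag else misses
  if (length(tags) == 0) {
    return(data.frame(category = character(0), count = integer(0),
                      percentage = numeric(0), stringsAsFactors = FALSE))
  }
  levels <- c("case_I", "case_II", "case_III", "case_IV")
  counts <- table(factor(tags, levels = levels))
  present <- counts[counts > 0]
  data.frame(
    category = names(present),
    count = as.integer(present),
    percentage = 100 * as.integer(present) / length(tags),
    stringsAsFactors = FALSE
  )
}

#' Compare estimated morphometrics against an allometric band
#'
#' For fish the body length L and height H follow approximately L = b * H
#' with a species-dependent proportionality b (about 2.5-3.0 for cultivated
#' carp). Each event's directly estimated length is checked against the
#' band `[b_low * H, b_high * H]`; events are then binned by height, and a
#' least-squares line is fitted to the per-bin medians (with per-bin
#' interquartile ranges for dispersion).
#'
#' @param events Data.frame with numeric `length` and `height` columns (e.g.
#'   from [events_table()]).
#' @param b_low,b_high Bounds of the allometric proportionality band.
#' @param bin_width_cm Height bin width, cm.
#' @return List of class `allometric_report` with components `events` (input
#'   plus `predicted_low`, `predicted_high`, `inside_band`), `bins`
#'   (per-bin n, median/IQR of height and length), and `fit` (`lm` of bin
#'   median length on bin median height, or `NULL` with fewer than 2 bins).
#' @export
allometric_compare <- function(events, b_low = 2.5, b_high = 3.0,
                               bin_width_cm = 1.5) {
  stopifnot(is.data.frame(events), all(c("length", "height") %in% names(events)))
  ev <- events[!is.na(events$length) & !is.na(events$height), , drop = FALSE]
  ev$predicted_low <- b_low * ev$height
  ev$predicted_high <- b_high * ev$height
  ev$inside_band <- ev$length >= ev$predicted_low &
    ev$length <= ev$predicted_high
  bin_id <- floor(ev$height / bin_width_cm)
  ids <- sort(unique(bin_id))
  bins <- do.call(rbind, lapply(ids, function(id) {
    g <- ev[bin_id == id, , drop = FALSE]
    data.frame(
      bin_low = id * bin_width_cm,
      n = nrow(g),
      height_median = stats::median(g$height),
      height_iqr = stats::IQR(g$height),
      length_median = stats::median(g$length),
      length_iqr = stats::IQR(g$length)
    )
  }))
  rownames(bins) <- NULL
  fit <- NULL
  if (!is.null(bins) && nrow(bins) >= 2) {
    fit <- stats::lm(length_median ~ height_median, data = bins)
  }
  structure(list(events = ev, bins = bins, fit = fit),
            class = "allometric_report")
}

#' @export
print.allometric_report <- function(x, ...) {
  cat(sprintf("<allometric_report> %d events, %d height bins; %.1f%% inside band\n",
              nrow(x$events), if (is.null(x$bins)) 0L else nrow(x$bins),
              if (nrow(x$events)) 100 * mean(x$events$inside_band) else NA))
  if (!is.null(x$fit)) {
    co <- stats::coef(x$fit)
    cat(sprintf("  bin-median fit: L = %.3f * H %+.3f\n", co[2], co[1]))
  } else {
    cat("  fewer than 2 bins: no regression\n")
  }
  invisible(x)
}

#' Plot an allometric comparison
#'
#' Scatter of estimated length against estimated height with the two
#' reference lines `L = b_low * H` and `L = b_high * H`, bin medians, and
#' the fitted bin-median regression.
#'
#' @param x An `allometric_report`.
#' @param b_low,b_high Reference proportionalities to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.allometric_report <- function(x, b_low = 2.5, b_high = 3.0, ...) {
  ev <- x$events
  graphics::plot(ev$height, ev$length, pch = 16, col = "grey50",
                 xlab = "estimated height (cm)",
                 ylab = "estimated length (cm)", ...)
  graphics::abline(0, b_low, lty = 2)
  graphics::abline(0, b_high, lty = 2)
  if (!is.null(x$bins)) {
    graphics::points(x$bins$height_median, x$bins$length_median,
                     pch = 17, col = "red")
    if (!is.null(x$fit)) graphics::abline(x$fit, col = "red")
  }
  invisible(x)
}
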