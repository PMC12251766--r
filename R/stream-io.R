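#' Write a beam stream to a plain-text log file
#'
#' The log dialect is one header line carrying the curtain configuration and
#' the ISO-8601 start time, followed by one line per frame:
#' `<frame_index> <A states>|<B states>`, where each states block is one
#' character per beam (`0` = interrupted, `1` = intact, bottom beam first).
#' Round-trips bit-exactly through [read_beam_log()].
#'
#' @param stream A [beam_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beam_log <- function(stream, path) {
  cfg <- stream$config
  header <- sprintf(
    paste0(
      "# fishcurtain-log v1 n_beams=%d beam_spacing_cm=%s array_gap_cm=%s ",
      "sampling_rate_hz=%s height_filter_threshold_cm=%s ",
      "height_correction_cm=%s upstream_label=%s start_time=%s"
    ),
    cfg$n_beams, format(cfg$beam_spacing), format(cfg$array_gap),
    format(cfg$sampling_rate), format(cfg$height_filter_threshold),
    format(cfg$height_correction), cfg$upstream_label,
    format_iso8601(stream$start_time)
  )
  n <- n_frames(stream)
  lines <- header
  if (n > 0) {
    a <- apply(stream$states_a, 1, paste, collapse = "")
    b <- apply(stream$states_b, 1, paste, collapse = "")
    lines <- c(header, sprintf("%d %s|%s", seq_len(n) - 1, a, b))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a beam stream from a log file
#'
#' Parses the dialect written by [write_beam_log()]. Malformed data lines
#' (wrong state-block width, non-binary characters, non-consecutive frame
#' indices) raise an error naming the offending line number.
#'
#' @param path Path to a log file.
#' @return A [beam_stream()].
#' @export
read_beam_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "# fishcurtain-log")) {
    stop(sprintf("'%s' is not a fishcurtain log (missing header)", path))
  }
  cfg <- parse_log_header(lines[1])
  data <- lines[-1]
  n <- length(data)
  if (n == 0) {
    return(beam_stream(cfg$config,
                       matrix(integer(0), 0, cfg$config$n_beams),
                       matrix(integer(0), 0, cfg$config$n_beams),
                       start_time = cfg$start_time))
  }
  parts <- strsplit(data, " ", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("malformed data line %d in '%s'", bad[1] + 1L, path))
  }
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  states <- vapply(parts, `[[`, "", 2)
  nb <- cfg$config$n_beams
  ok <- grepl(sprintf("^[01]{%d}\\|[01]{%d}$", nb, nb), states)
  if (!all(ok)) {
    stop(sprintf(
      "line %d in '%s': expected %d+%d binary state characters",
      which(!ok)[1] + 1L, path, nb, nb
    ))
  }
  if (anyNA(idx) || !identical(idx, seq_len(n) - 1L)) {
    first <- which(is.na(idx) | idx != seq_len(n) - 1L)[1]
    stop(sprintf("line %d in '%s': frame_index not consecutive from 0",
                 first + 1L, path))
  }
  chars <- matrix(
    as.integer(unlist(strsplit(states, "", fixed = TRUE), use.names = FALSE) == "1"),
    nrow = n, byrow = TRUE
  )
  beam_stream(cfg$config,
              chars[, seq_len(nb), drop = FALSE],
              chars[, nb + 1L + seq_len(nb), drop = FALSE],
              start_time = cfg$start_time)
}

parse_log_header <- function(header) {
  kv_pat <- "([a-z_]+)=([^ ]+)"
  m <- gregexpr(kv_pat, header)[[1]]
  keys <- character(0); vals <- character(0)
  for (i in seq_along(m)) {
    piece <- substr(header, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", piece, fixed = TRUE)
    keys <- c(keys, substr(piece, 1, eq - 1))
    vals <- c(vals, substr(piece, eq + 1, nchar(piece)))
  }
  names(vals) <- keys
  need <- c("n_beams", "beam_spacing_cm", "array_gap_cm", "sampling_rate_hz",
            "start_time")
  if (!all(need %in% keys)) {
    stop("log header is missing required keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  }
  config <- sensor_config(
    n_beams = as.integer(vals[["n_beams"]]),
    beam_spacing = as.numeric(vals[["beam_spacing_cm"]]),
    array_gap = as.numeric(vals[["array_gap_cm"]]),
    sampling_rate = as.numeric(vals[["sampling_rate_hz"]]),
    height_filter_threshold =
      as.numeric(vals["height_filter_threshold_cm"] %|na|% "1.5"),
    height_correction =
      as.numeric(vals["height_correction_cm"] %|na|%
                   (as.numeric(vals[["beam_spacing_cm"]]) / 2)),
    upstream_label = as.character(vals["upstream_label"] %|na|% "A")
  )
  list(config = config, start_time = parse_iso8601(vals[["start_time"]]))
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Check beam health over a fish-free window
#'
#' Under fish-free conditions every beam should read intact (1) almost
#' always. A beam that is intact in fewer than `min_intact_frac` of the
#' window frames — stuck interrupted, or flickering — is flagged.
#'
#' @param stream A [beam_stream()] recorded with no fish present.
#' @param window_frames Number of leading frames to inspect.
#' @param min_intact_frac Minimum acceptable intact fraction (default 0.99).
#' @return A data.frame with columns `array`, `beam`, `frac_intact`,
#'   `status` ("OK" or "FLAGGED"), one row per beam of each array.
#' @export
check_calibration <- function(stream, window_frames = n_frames(stream),
                              min_intact_frac = 0.99) {
  stopifnot(window_frames >= 1)
  if (n_frames(stream) < window_frames) {
    stop("stream shorter than the requested calibration window")
  }
  cfg <- stream$config
  win <- seq_len(window_frames)
  frac <- c(colMeans(stream$states_a[win, , drop = FALSE]),
            colMeans(stream$states_b[win, , drop = FALSE]))
  out <- data.frame(
    array = rep(cfg$array_labels, each = cfg$n_beams),
    beam = rep(seq_len(cfg$n_beams), 2),
    frac_intact = frac,
    status = ifelse(frac >= min_intact_frac, "OK", "FLAGGED"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write the raw frame slice of a passage event to a clip file
#'
#' The clip uses the same dialect as [write_beam_log()], with frame indices
#' rebased to 0 and the header start time set to the event timestamp, so a
#' clip is itself a valid log.
#'
#' @param event A `passage_event` (from [filter_events()] or
#'   [classify_stream()]).
#' @param clip_dir Directory for clip files (created if needed).
#' @return The clip file path, invisibly.
#' @export
write_event_clip <- function(event, clip_dir) {
  stopifnot(inherits(event, "passage_event"))
  if (!dir.exists(clip_dir)) dir.create(clip_dir, recursive = TRUE)
  cand <- event$candidate
  clip_stream <- beam_stream(cand$config, cand$states_a, cand$states_b,
                             start_time = event$timestamp)
  fname <- sprintf("event_%s.txt",
                   format(event$timestamp, "%Y%m%dT%H%M%OS3", tz = "UTC"))
  path <- file.path(clip_dir, fname)
  write_beam_log(clip_stream, path)
  invisible(path)
}

#' Append a summary record to the central event log
#'
#' The event log is a TSV with one line per accepted passage: timestamp,
#' direction label, mean velocity (cm/s), length (cm), height (cm), event
#' id, and clip path. Numeric values are written at 0.01 precision.
#'
#' @param record A one-row data.frame as produced by [event_log_record()].
#' @param path Path to the event log file (created on first append).
#' @return `path`, invisibly.
#' @export
append_event_log <- function(record, path) {
  line <- sprintf(
    "%s\t%s\t%.2f\t%.2f\t%.2f\t%s\t%s",
    format_iso8601(record$timestamp), record$direction_label,
    record$velocity, record$length, record$height,
    record$event_id, record$source_clip
  )
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Summarise a passage event as an event-log record
#'
#' @param event A `passage_event`.
#' @param config The [sensor_config()] (for direction labels).
#' @param event_id Identifier string.
#' @param source_clip Relative path of the event's clip file.
#' @return One-row data.frame with columns `timestamp`, `direction`,
#'   `direction_label`, `velocity`, `length`, `height`, `event_id`,
#'   `source_clip`.
#' @export
event_log_record <- function(event, config, event_id = "", source_clip = "") {
  stopifnot(inherits(event, "passage_event"))
  data.frame(
    timestamp = event$timestamp,
    direction = event$direction,
    direction_label = direction_label(event$direction, config),
    velocity = event$velocity$mean,
    length = event$morphometrics$length,
    height = event$morphometrics$height,
    event_id = event_id,
    source_clip = source_clip,
    stringsAsFactors = FALSE
  )
}

#' Read a central event log back into a data.frame
#'
#' @param path Path to an event log written by [append_event_log()].
#' @return Data.frame with one row per event; `timestamp` is POSIXct (UTC).
#' @export
read_event_log <- function(path) {
  if (!file.exists(path) || length(readLines(path)) == 0) {
    return(data.frame(
      timestamp = as.POSIXct(character(0), tz = "UTC"),
      direction_label = character(0), velocity = numeric(0),
      length = numeric(0), height = numeric(0),
      event_id = character(0), source_clip = character(0),
      stringsAsFactors = FALSE
    ))
  }
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "", quote = "",
                           col.names = c("timestamp", "direction_label",
                                         "velocity", "length", "height",
                                         "event_id", "source_clip"),
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "numeric", "character",
                                          "character"))
  raw$timestamp <- as.POSIXct(raw$timestamp,
                              format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  raw
}
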