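#' Sensor curtain configuration
#'
#' Geometry and timing constants of a two-array infrared light curtain.
#' The curtain consists of two vertical beam arrays (labelled A and B along
#' the positive travel axis) separated by a fixed horizontal gap. Beam index
#' 1 is the bottom-most beam; beam j sits at vertical coordinate
#' `(j - 1) * beam_spacing` cm.
#'
#' @param n_beams Number of beams per array (>= 2 for a usable curtain).
#' @param beam_spacing Vertical distance between adjacent beams, cm.
#' @param array_gap Horizontal distance D between the two arrays, cm.
#' @param sampling_rate Sampling frequency f of the beam-state stream, Hz.
#' @param height_filter_threshold Minimum biologically plausible body height,
#'   cm; events with a smaller estimated height are rejected by
#'   [filter_events()].
#' @param height_correction Additive correction applied to the raw vertical
#'   beam extent when estimating body height, cm. Defaults to half the beam
#'   spacing, which compensates the zero height reported when only a single
#'   beam is interrupted.
#' @param array_labels Character pair naming the two arrays; the first label
#'   is the array first met by a fish travelling in the positive direction.
#' @param upstream_label Which of the two labels faces upstream. Used only
#'   to translate signed directions into "upstream"/"downstream" strings.
#'
#' @return An object of class `sensor_config`.
#' @seealso [full_scale_config()], [mini_config()], [read_sensor_config()]
#' @export
sensor_config <- function(n_beams = 40,
                          beam_spacing = 1.5,
                          array_gap = 6,
                          sampling_rate = 50,
                          height_filter_threshold = 1.5,
                          height_correction = beam_spacing / 2,
                          array_labels = c("A", "B"),
                          upstream_label = array_labels[1]) {
  stopifnot(
    length(n_beams) == 1, n_beams >= 1, n_beams == as.integer(n_beams),
    beam_spacing > 0, array_gap > 0, sampling_rate > 0,
    height_filter_threshold >= 0, height_correction >= 0,
    length(array_labels) == 2, !anyDuplicated(array_labels),
    upstream_label %in% array_labels
  )
  structure(
    list(
      n_beams = as.integer(n_beams),
      beam_spacing = beam_spacing,
      array_gap = array_gap,
      sampling_rate = sampling_rate,
      height_filter_threshold = height_filter_threshold,
      height_correction = height_correction,
      array_labels = as.character(array_labels),
      upstream_label = as.character(upstream_label)
    ),
    class = "sensor_config"
  )
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf(
    "<sensor_config> %d beams/array, %.3g cm pitch, arrays %.3g cm apart, %g Hz\n",
    x$n_beams, x$beam_spacing, x$array_gap, x$sampling_rate
  ))
  cat(sprintf(
    "  detection span %.3g cm; height filter >= %.3g cm (+%.3g cm correction); upstream = %s\n",
    detection_span(x), x$height_filter_threshold, x$height_correction,
    x$upstream_label
  ))
  invisible(x)
}

#' Default full-scale curtain profile
#'
#' 40 beams per array at 1.5 cm pitch (60 cm detection span), arrays 6 cm
#' apart, sampled at 50 Hz.
#' @param ... Overrides passed to [sensor_config()].
#' @return A `sensor_config`.
#' @export
full_scale_config <- function(...) {
  sensor_config(n_beams = 40, ...)
}

#' Default mini curtain profile
#'
#' 8 beams per array, otherwise identical to the full-scale profile.
#' @param ... Overrides passed to [sensor_config()].
#' @return A `sensor_config`.
#' @export
mini_config <- function(...) {
  sensor_config(n_beams = 8, ...)
}

#' Vertical beam coordinates
#'
#' @param config A [sensor_config()].
#' @return Numeric vector of length `n_beams`: vertical positions (cm) of the
#'   beams, bottom first, i.e. `0, s, 2s, ..., (n - 1) s`.
#' @export
beam_positions <- function(config) {
  stopifnot(inherits(config, "sensor_config"))
  (seq_len(config$n_beams) - 1) * config$beam_spacing
}

#' Advertised detection span of the curtain
#'
#' Total detection height covered by one array at the stated element pitch,
#' computed as `n_beams * beam_spacing` (so the full-scale profile yields
#' 60 cm).
#'
#' @param config A [sensor_config()].
#' @return Span in cm.
#' @export
detection_span <- function(config) {
  stopifnot(inherits(config, "sensor_config"))
  config$n_beams * config$beam_spacing
}

#' Smallest body height guaranteed to hit a minimum number of beams
#'
#' Returns the smallest body height h such that a closed vertical interval of
#' length h intersects at least `min_beams` beam lines at *every* vertical
#' offset. The closed form is `min_beams * beam_spacing`: an interval of
#' length k*s always contains at least k grid points of pitch s, while any
#' shorter interval can be placed to contain only k - 1. The `"sweep"` method
#' verifies this geometrically by brute force, sweeping candidate heights and
#' vertical offsets on fine grids.
#'
#' @param config A [sensor_config()].
#' @param min_beams Required number of intersected beams (>= 1).
#' @param method `"analytic"` (closed form, default) or `"sweep"`
#'   (brute-force offset sweep).
#' @param height_step Candidate height resolution for the sweep, cm.
#' @param offset_step Vertical offset resolution for the sweep, cm.
#' @return Height in cm.
#' @export
min_guaranteed_height <- function(config, min_beams,
                                  method = c("analytic", "sweep"),
                                  height_step = 0.1,
                                  offset_step = 0.01) {
  stopifnot(inherits(config, "sensor_config"), min_beams >= 1)
  if (min_beams > config$n_beams) {
    stop("min_beams exceeds the number of beams in the array")
  }
  method <- match.arg(method)
  s <- config$beam_spacing
  if (method == "analytic") {
    return(min_beams * s)
  }
  # Brute force: a body [off, off + h] intersects beam lines at multiples of
  # s; by periodicity only offsets in [0, s) need checking.
  offsets <- seq(0, s, by = offset_step)
  offsets <- offsets[offsets < s]
  heights <- seq(height_step, (min_beams + 1) * s, by = height_step)
  for (h in heights) {
    n_hit <- floor((offsets + h) / s) - ceiling(offsets / s) + 1
    if (all(n_hit >= min_beams)) {
      return(h)
    }
  }
  stop("no candidate height satisfied the requirement (sweep range too short)")
}

#' Read a curtain configuration from a YAML file
#'
#' Recognised keys: `n_beams`, `beam_spacing_cm`, `array_gap_cm`,
#' `sampling_rate_hz`, `height_filter_threshold_cm`, `height_correction_cm`,
#' `upstream_label`. Missing keys fall back to the full-scale defaults.
#'
#' @param path Path to a YAML config file.
#' @return A `sensor_config`.
#' @export
read_sensor_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  map <- c(
    n_beams = "n_beams", beam_spacing = "beam_spacing_cm",
    array_gap = "array_gap_cm", sampling_rate = "sampling_rate_hz",
    height_filter_threshold = "height_filter_threshold_cm",
    height_correction = "height_correction_cm",
    upstream_label = "upstream_label"
  )
  for (arg in names(map)) {
    if (!is.null(raw[[map[[arg]]]])) args[[arg]] <- raw[[map[[arg]]]]
  }
  do.call(sensor_config, args)
}

# Map a signed direction (+1 = A-to-B travel) to the configured
# upstream/downstream label.
direction_label <- function(direction, config) {
  stopifnot(direction %in% c(-1L, 1L))
  toward <- if (direction > 0) config$array_labels[2] else config$array_labels[1]
  if (identical(toward, config$upstream_label)) "upstream" else "downstream"
}
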