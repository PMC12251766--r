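#' Specification of a simulated fish
#'
#' A fish is modelled as a rigid 2D silhouette (ellipse or rectangle of the
#' given length and height) moving horizontally at constant speed,
#' perpendicular to the curtain plane. `entry_time` is the instant the nose
#' reaches the first array met along the travel direction. An optional
#' `reverse_time` makes the fish turn around instantaneously at that instant
#' (used to synthesise self-cancelling bidirectional passages).
#'
#' @param length Body length, cm.
#' @param height Body height, cm.
#' @param depth_center Vertical coordinate of the body midline, cm (beam 1
#'   sits at 0).
#' @param speed Swimming speed, cm/s.
#' @param direction +1 = array A to array B, -1 = the reverse.
#' @param shape `"ellipse"` (default) or `"rectangle"`.
#' @param entry_time Seconds from stream start when the nose reaches the
#'   first array.
#' @param reverse_time Optional absolute time (s from stream start) at which
#'   the fish reverses direction; `NULL` for a straight crossing.
#' @return An object of class `fish_spec`.
#' @export
fish_spec <- function(length, height, depth_center, speed,
                      direction = 1L, shape = c("ellipse", "rectangle"),
                      entry_time = 1, reverse_time = NULL) {
  shape <- match.arg(shape)
  stopifnot(length > 0, height > 0, speed > 0, direction %in% c(-1L, 1L),
            entry_time >= 0)
  structure(
    list(length = length, height = height, depth_center = depth_center,
         speed = speed, direction = as.integer(direction), shape = shape,
         entry_time = entry_time, reverse_time = reverse_time),
    class = "fish_spec"
  )
}

# Horizontal body-centre position at times t (s from stream start).
fish_center_x <- function(fish, config, t) {
  d <- fish$direction
  x_entry <- if (d > 0) -fish$length / 2 else config$array_gap + fish$length / 2
  cx <- x_entry + d * fish$speed * (t - fish$entry_time)
  if (!is.null(fish$reverse_time)) {
    rt <- fish$reverse_time
    x_rev <- x_entry + d * fish$speed * (rt - fish$entry_time)
    after <- t > rt
    cx[after] <- x_rev - d * fish$speed * (t[after] - rt)
  }
  cx
}

# Frames x beams logical matrix of beams interrupted by `fish` at one array.
fish_interruptions <- function(fish, config, t, x_array) {
  eps <- 1e-9
  cx <- fish_center_x(fish, config, t)
  del <- abs(cx - x_array)
  ydist <- abs(beam_positions(config) - fish$depth_center)
  covered <- del <= fish$length / 2 + eps
  if (fish$shape == "rectangle") {
    half_h <- ifelse(covered, fish$height / 2, -1)
  } else {
    frac <- pmin(1, (del / (fish$length / 2))^2)
    half_h <- ifelse(covered, (fish$height / 2) * sqrt(1 - frac), -1)
  }
  outer(half_h + eps, ydist, `>=`)
}

#' Simulate a single fish passage
#'
#' Produces a noise-free beam stream in which beam j of an array is
#' interrupted at frame k exactly when the rigid body covers the point
#' (array x-position, beam height) at t = k / f. Array A sits at x = 0,
#' array B at x = `array_gap`. Deterministic given its inputs.
#'
#' @param fish A [fish_spec()].
#' @param config A [sensor_config()].
#' @param stream_length_s Stream duration, s.
#' @param start_time Wall-clock time of frame 0.
#' @return List with components `stream` (a [beam_stream()]) and `truth`
#'   (one-row data.frame ground-truth record).
#' @export
simulate_passage <- function(fish, config, stream_length_s,
                             start_time = as.POSIXct("2025-06-01 10:00:00",
                                                     tz = "UTC")) {
  n <- floor(stream_length_s * config$sampling_rate)
  t <- (seq_len(n) - 1) / config$sampling_rate
  int_a <- fish_interruptions(fish, config, t, 0)
  int_b <- fish_interruptions(fish, config, t, config$array_gap)
  stream <- beam_stream(config, 1L - (int_a * 1L), 1L - (int_b * 1L),
                        start_time = start_time)
  truth <- truth_record(fish, start_time,
                        scenario_tag = "clean",
                        expected_detectable = any(int_a) || any(int_b))
  list(stream = stream, truth = truth)
}

truth_record <- function(fish, start_time, scenario_tag, expected_detectable) {
  data.frame(
    length = fish$length, height = fish$height,
    depth_center = fish$depth_center, speed = fish$speed,
    direction = fish$direction, shape = fish$shape,
    entry_time = fish$entry_time,
    time = start_time + fish$entry_time,
    scenario_tag = scenario_tag,
    expected_detectable = expected_detectable,
    stringsAsFactors = FALSE
  )
}

#' Noise specification for scenario simulation
#'
#' @param spurious_rate Expected spurious single-beam, single-frame blips
#'   per second (Poisson).
#' @param surface_band_beams Number of top-most beams interrupted by a
#'   surface-distortion band (0 = no band). The band affects both arrays.
#' @param surface_band_start Band onset, s from stream start.
#' @param surface_band_duration Band duration, s.
#' @param seed RNG seed for the spurious-blip process (mandatory when
#'   `spurious_rate > 0`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(spurious_rate = 0, surface_band_beams = 0L,
                       surface_band_start = 0, surface_band_duration = 0,
                       seed = NULL) {
  stopifnot(spurious_rate >= 0, surface_band_beams >= 0,
            surface_band_duration >= 0)
  if (spurious_rate > 0 && is.null(seed)) {
    stop("a seed is required when spurious_rate > 0")
  }
  structure(
    list(spurious_rate = spurious_rate,
         surface_band_beams = as.integer(surface_band_beams),
         surface_band_start = surface_band_start,
         surface_band_duration = surface_band_duration,
         seed = seed),
    class = "noise_spec"
  )
}

#' Simulate a multi-fish scenario with optional noise
#'
#' Superimposes the passages of several fish (a beam is interrupted when any
#' body, the surface band, or a spurious blip covers it), producing one
#' stream plus a ground-truth table. Scenario tags label each fish with the
#' error mechanism it exercises:
#'
#' * `clean` — unobstructed single crossing.
#' * `case_I` — crossing masked by a surface-distortion band.
#' * `case_II` — second fish masked by the band left by a preceding fish.
#' * `case_III` — two fish with overlapping crossing intervals at different
#'   depths (merged into one candidate).
#' * `case_IV` — bidirectional (turnaround) movement that self-cancels.
#' * `noise_only` — no fish, only spurious blips.
#'
#' @param fishes List of [fish_spec()] objects (possibly empty).
#' @param config A [sensor_config()].
#' @param stream_length_s Stream duration, s.
#' @param noise Optional [noise_spec()].
#' @param tags Character vector of scenario tags, one per fish (recycled if
#'   length 1).
#' @param expected_detectable Logical vector, one per fish; defaults to
#'   `TRUE` except for fish tagged `case_II`, whose own signal is entirely
#'   absorbed by the surface band left by the preceding fish.
#' @param start_time Wall-clock time of frame 0.
#' @return List with `stream` (a [beam_stream()]) and `truth` (data.frame,
#'   one row per fish).
#' @export
simulate_scenario <- function(fishes, config, stream_length_s,
                              noise = NULL, tags = "clean",
                              expected_detectable = NULL,
                              start_time = as.POSIXct("2025-06-01 10:00:00",
                                                      tz = "UTC")) {
  n <- floor(stream_length_s * config$sampling_rate)
  t <- (seq_len(n) - 1) / config$sampling_rate
  nb <- config$n_beams
  int_a <- matrix(FALSE, n, nb)
  int_b <- matrix(FALSE, n, nb)
  tags <- rep_len(tags, length(fishes))
  for (fish in fishes) {
    int_a <- int_a | fish_interruptions(fish, config, t, 0)
    int_b <- int_b | fish_interruptions(fish, config, t, config$array_gap)
  }
  if (!is.null(noise)) {
    if (noise$surface_band_beams > 0 && noise$surface_band_duration > 0) {
      band_frames <- t >= noise$surface_band_start &
        t <= noise$surface_band_start + noise$surface_band_duration
      band_beams <- (nb - noise$surface_band_beams + 1L):nb
      int_a[band_frames, band_beams] <- TRUE
      int_b[band_frames, band_beams] <- TRUE
    }
    if (noise$spurious_rate > 0) {
      blips <- with_seed(noise$seed, {
        k <- stats::rpois(1, noise$spurious_rate * stream_length_s)
        data.frame(
          frame = sample.int(n, k, replace = TRUE),
          beam = sample.int(nb, k, replace = TRUE),
          array = sample(c("a", "b"), k, replace = TRUE)
        )
      })
      for (i in seq_len(nrow(blips))) {
        if (blips$array[i] == "a") {
          int_a[blips$frame[i], blips$beam[i]] <- TRUE
        } else {
          int_b[blips$frame[i], blips$beam[i]] <- TRUE
        }
      }
    }
  }
  if (n > 0 && all(rowSums(int_a) + rowSums(int_b) > 0)) {
    stop("scenario leaves no intact frame in the stream; extend stream_length_s")
  }
  stream <- beam_stream(config, 1L - (int_a * 1L), 1L - (int_b * 1L),
                        start_time = start_time)
  if (length(fishes) == 0) {
    truth <- truth_record(fish_spec(1, 1, 0, 1), start_time, "noise_only",
                          FALSE)[0, ]
  } else {
    if (is.null(expected_detectable)) {
      expected_detectable <- tags != "case_II"
    }
    truth <- do.call(rbind, Map(function(fish, tag, det) {
      truth_record(fish, start_time, tag, det)
    }, fishes, tags, expected_detectable))
  }
  list(stream = stream, truth = truth)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Canonical error-scenario presets
#'
#' Builds the fish/noise composition for one of the named scenarios, using
#' the larger dummy-replica geometry (16.5 cm x 6.4 cm ellipse, 30 cm/s)
#' vertically centred in the curtain.
#'
#' @param case One of `"clean"`, `"case_I"`, `"case_II"`, `"case_III"`,
#'   `"case_IV"`, `"noise_only"`.
#' @param config A [sensor_config()].
#' @param seed RNG seed for any stochastic component.
#' @return List with `fishes`, `noise`, `tags`, `expected_detectable`, and
#'   `stream_length_s`, ready for [simulate_scenario()].
#' @export
scenario_preset <- function(case = c("clean", "case_I", "case_II", "case_III",
                                     "case_IV", "noise_only"),
                            config = full_scale_config(), seed = 1L) {
  case <- match.arg(case)
  mid <- (config$n_beams - 1) * config$beam_spacing / 2
  base <- function(...) {
    args <- utils::modifyList(
      list(length = 16.5, height = 6.4, depth_center = mid, speed = 30),
      list(...)
    )
    do.call(fish_spec, args)
  }
  cross_s <- (16.5 + config$array_gap) / 30
  switch(case,
    clean = list(
      fishes = list(base(entry_time = 1)),
      noise = NULL, tags = "clean", expected_detectable = TRUE,
      stream_length_s = 2 + cross_s
    ),
    case_I = list(
      fishes = list(base(entry_time = 2)),
      noise = noise_spec(surface_band_beams = config$n_beams,
                         surface_band_start = 1.5,
                         surface_band_duration = cross_s + 1.5),
      tags = "case_I", expected_detectable = TRUE,
      stream_length_s = 5 + cross_s
    ),
    case_II = list(
      fishes = list(base(entry_time = 1), base(entry_time = 4)),
      noise = noise_spec(surface_band_beams = config$n_beams,
                         surface_band_start = 3.5,
                         surface_band_duration = cross_s + 1.5),
      tags = c("clean", "case_II"), expected_detectable = c(TRUE, FALSE),
      stream_length_s = 7 + cross_s
    ),
    case_III = list(
      fishes = list(base(entry_time = 1, depth_center = mid - 9),
                    base(entry_time = 1.2, depth_center = mid + 9)),
      noise = NULL, tags = "case_III", expected_detectable = c(TRUE, TRUE),
      stream_length_s = 3 + cross_s
    ),
    case_IV = list(
      fishes = list(base(entry_time = 1,
                         reverse_time = 1 + (config$array_gap + 2) / 30)),
      noise = NULL, tags = "case_IV", expected_detectable = TRUE,
      stream_length_s = 3 + cross_s
    ),
    noise_only = list(
      fishes = list(),
      noise = noise_spec(spurious_rate = 2, seed = seed),
      tags = character(0), expected_detectable = logical(0),
      stream_length_s = 10
    )
  )
}

#' Simulate the controlled dummy-replica trial
#'
#' Emulates the benchmark protocol used to validate beam-break counters
#' under controlled conditions: a rigid replica of known size is passed
#' through the curtain repeatedly in both directions. Passages are placed
#' on one long noise-free stream, several seconds apart, vertically centred
#' in the curtain, with a deterministic sub-frame phase spread so the
#' quantization of every passage differs.
#'
#' @param config A [sensor_config()].
#' @param length,height Replica dimensions, cm (defaults: the larger
#'   16.5 cm x 6.4 cm replica).
#' @param n_per_direction Passages per travel direction.
#' @param speed Passage speed, cm/s.
#' @param spacing_s Seconds between consecutive passages.
#' @param shape Replica silhouette shape.
#' @param start_time Wall-clock time of frame 0.
#' @return List with `stream` (one [beam_stream()] containing all passages)
#'   and `truth` (one row per passage).
#' @export
simulate_dummy_trial <- function(config = full_scale_config(),
                                 length = 16.5, height = 6.4,
                                 n_per_direction = 10, speed = 30,
                                 spacing_s = 5, shape = "ellipse",
                                 start_time = as.POSIXct("2025-06-01 10:00:00",
                                                         tz = "UTC")) {
  mid <- (config$n_beams - 1) * config$beam_spacing / 2
  n_total <- 2 * n_per_direction
  fishes <- lapply(seq_len(n_total), function(k) {
    fish_spec(length = length, height = height, depth_center = mid,
              speed = speed,
              direction = if (k <= n_per_direction) 1L else -1L,
              shape = shape,
              entry_time = spacing_s * (k - 1) + 1 + (k - 1) * 0.0137)
  })
  simulate_scenario(fishes, config,
                    stream_length_s = spacing_s * n_total + 2,
                    tags = "clean", start_time = start_time)
}
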