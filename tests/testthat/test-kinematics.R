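make_two_array_event <- function(first_a, last_a, first_b, last_b, n,
                                 cfg = full_scale_config(), beam = 20) {
  a <- intact(n, cfg); b <- intact(n, cfg)
  if (!is.na(first_a)) a[first_a:last_a, beam] <- 0L
  if (!is.na(first_b)) b[first_b:last_b, beam] <- 0L
  candidate_from_states(a, b, cfg)
}

test_that("direction estimates follow first/last activation order", {
  # A first active at frame 10, B at 16 -> entry +1
  ev <- make_two_array_event(11, 30, 17, 36, 40)
  d <- estimate_directions(ev)
  expect_equal(d$entry, 1L)
  expect_equal(d$exit, 1L)

  # simultaneous first activation -> entry 0
  ev <- make_two_array_event(11, 30, 11, 36, 40)
  expect_equal(estimate_directions(ev)$entry, 0L)

  # array B never interrupted -> both components 0
  ev <- make_two_array_event(11, 30, NA, NA, 40)
  d <- estimate_directions(ev)
  expect_equal(c(d$entry, d$exit), c(0L, 0L))

  # simulated fish travelling B -> A
  cfg <- full_scale_config()
  sim <- simulate_passage(dummy_fish(direction = -1), cfg, 3)
  ev <- segment_events(sim$stream)[[1]]
  d <- estimate_directions(ev)
  expect_equal(c(d$entry, d$exit), c(-1L, -1L))
})

test_that("velocity is D / dt with undefined zero-delay components", {
  # entry delay 6 frames at 50 Hz over 6 cm -> 50 cm/s
  ev <- make_two_array_event(11, 30, 17, 36, 40)
  v <- estimate_velocities(ev)
  expect_equal(v$entry, 50)
  expect_equal(v$exit, 50)
  expect_equal(v$mean, 50)

  # zero-frame entry delay -> entry undefined, exit still defined
  ev <- make_two_array_event(11, 30, 11, 36, 40)
  v <- estimate_velocities(ev)
  expect_true(is.na(v$entry))
  expect_equal(v$exit, 50)
  expect_equal(v$mean, 50)

  # simulated 30 cm/s fish: recovered within one frame-quantization step
  cfg <- full_scale_config()
  sim <- simulate_passage(dummy_fish(entry_time = 1.013), cfg, 3)
  ev <- segment_events(sim$stream)[[1]]
  v <- estimate_velocities(ev)
  d_true <- cfg$array_gap / 30 * cfg$sampling_rate
  expect_gte(v$mean, cfg$array_gap * cfg$sampling_rate / (d_true + 1))
  expect_lte(v$mean, cfg$array_gap * cfg$sampling_rate / (d_true - 1))
})

test_that("velocity recovery stays inside the quantization bound (5-100 cm/s)", {
  cfg <- full_scale_config()
  set.seed(101)
  for (i in 1:40) {
    speed <- runif(1, 5, 100)
    dir <- sample(c(-1L, 1L), 1)
    fish <- fish_spec(length = runif(1, 8, 20), height = runif(1, 3.5, 8),
                      depth_center = runif(1, 15, 45), speed = speed,
                      direction = dir, entry_time = runif(1, 0.5, 1))
    sim <- simulate_passage(fish, cfg,
                            fish$entry_time + (fish$length + 6) / speed + 1)
    ev <- segment_events(sim$stream)[[1]]
    v <- estimate_velocities(ev)
    d_true <- cfg$array_gap / speed * cfg$sampling_rate
    lo <- cfg$array_gap * cfg$sampling_rate / (d_true + 1)
    hi <- cfg$array_gap * cfg$sampling_rate / (d_true - 1)
    expect_gte(v$entry, lo); expect_lte(v$entry, hi)
    expect_gte(v$exit, lo); expect_lte(v$exit, hi)
    expect_gte(v$mean, lo); expect_lte(v$mean, hi)
  }
})

test_that("direction recovery is exact for clean passages at any phase", {
  cfg <- full_scale_config()
  set.seed(202)
  phases <- runif(50, 0.5, 1.5)
  for (dir in c(1L, -1L)) {
    for (ph in phases) {
      sim <- simulate_passage(dummy_fish(direction = dir, entry_time = ph),
                              cfg, 3.5)
      ev <- segment_events(sim$stream)[[1]]
      d <- estimate_directions(ev)
      expect_equal(d$entry, dir)
      expect_equal(d$exit, dir)
    }
  }
})

test_that("length is mean velocity times occupancy duration", {
  cfg <- full_scale_config()
  # V = 30 cm/s, array A spans 27 frames -> length_a = 16.2 cm
  a <- intact(140, cfg); b <- intact(140, cfg)
  a[101:128, 20] <- 0L
  b[111:138, 20] <- 0L
  ev <- candidate_from_states(a, b, cfg)
  v <- list(entry = 30, exit = 30, mean = 30)
  l <- estimate_length(ev, v)
  expect_equal(l$length_a, 16.2)
  expect_equal(l$length_b, 16.2)
  expect_equal(l$length, 16.2)

  # zero-span occupancy -> length 0; undefined velocity -> undefined length
  a <- intact(10, cfg); a[5, 20] <- 0L
  ev1 <- candidate_from_states(a, intact(10, cfg), cfg)
  expect_equal(estimate_length(ev1, v)$length_a, 0)
  expect_true(is.na(estimate_length(ev1, list(mean = NA_real_))$length))
})

test_that("length recovery of rigid fish respects the quantization bound", {
  cfg <- full_scale_config()
  set.seed(303)
  # speeds with integral inter-array frame delay: the velocity estimate is
  # exact and only the occupancy-span quantization (<= 2 frames) remains
  for (speed in c(60, 50, 30, 20, 15, 10)) {
    for (rep in 1:5) {
      L <- runif(1, 8, 20)
      fish <- fish_spec(length = L, height = 6.4, depth_center = 29.25,
                        speed = speed, shape = "rectangle",
                        entry_time = runif(1, 0.5, 1))
      sim <- simulate_passage(fish, cfg,
                              fish$entry_time + (L + 6) / speed + 1)
      ev <- segment_events(sim$stream)[[1]]
      v <- estimate_velocities(ev)
      expect_equal(v$mean, speed)
      l <- estimate_length(ev, v)
      expect_lte(abs(l$length - L), 2 * speed / cfg$sampling_rate + 1e-6)
    }
  }
})

test_that("height is the corrected vertical beam extent", {
  cfg <- full_scale_config()
  # single interrupted beam -> 0 + correction
  a <- intact(10, cfg); a[3:6, 12] <- 0L
  ev <- candidate_from_states(a, intact(10, cfg), cfg)
  expect_equal(estimate_height(ev), 0.75)

  # beams at indices 10-13 (0-based) -> 4.5 + 0.75
  a <- intact(10, cfg); a[3:6, 11:14] <- 0L
  ev <- candidate_from_states(a, intact(10, cfg), cfg)
  expect_equal(estimate_height(ev), 5.25)

  # union over both arrays
  a <- intact(10, cfg); b <- intact(10, cfg)
  a[3:6, 11] <- 0L; b[4:7, 14] <- 0L
  ev <- candidate_from_states(a, b, cfg)
  expect_equal(estimate_height(ev), 5.25)

  expect_error(
    estimate_height(candidate_from_states(intact(5, cfg), intact(5, cfg), cfg)),
    "no interrupted"
  )
})

test_that("height estimates stay in the sharp lattice bounds at all offsets", {
  cfg <- full_scale_config()
  s <- cfg$beam_spacing
  for (h in c(2.1, 3.0, 4.4, 6.4, 9.0)) {
    allowed <- height_estimate_set(h, s, cfg$height_correction)
    for (off in seq(0, s, length.out = 31)) {
      fish <- fish_spec(length = 12, height = h, depth_center = 20 + off,
                        speed = 30, shape = "rectangle")
      sim <- simulate_passage(fish, cfg, 2.5)
      ev <- segment_events(sim$stream)[[1]]
      expect_true(any(abs(estimate_height(ev) - allowed) < 1e-9))
    }
  }
  # the stated example: a 6.4 cm body reads between 5.25 and 6.75 cm
  expect_equal(height_estimate_set(6.4, s, cfg$height_correction),
               c(5.25, 6.75))
})

test_that("silhouette reconstruction maps frames to dx = V/f columns", {
  cfg <- full_scale_config()
  sim <- simulate_passage(dummy_fish(), cfg, 3)
  ev <- segment_events(sim$stream)[[1]]
  v <- estimate_velocities(ev)
  sil <- reconstruct_silhouette(ev, v)
  expect_s3_class(sil, "silhouette")
  expect_equal(sil$dx, v$mean / cfg$sampling_rate)
  # V = 50 cm/s at 50 Hz gives a 1 cm step
  expect_equal(reconstruct_silhouette(ev, list(mean = 50))$dx, 1)

  # ellipse silhouette has a unimodal per-column height profile
  prof <- rowSums(sil$occupancy)
  peak <- which.max(prof)
  expect_true(all(diff(prof[1:peak]) >= 0))
  expect_true(all(diff(prof[peak:length(prof)]) <= 0))

  # extent ties to the occupancy bounding box via dx and beam pitch
  expect_equal(unname(sil$extent["length"]), (nrow(sil$occupancy) - 1) * sil$dx)

  # reversed direction draws the nose first (columns flipped)
  sil_rev <- reconstruct_silhouette(ev, v, direction = -1L)
  expect_identical(sil_rev$occupancy,
                   sil$occupancy[rev(seq_len(nrow(sil$occupancy))), ])

  # single-frame event: one-column silhouette with zero length extent
  a <- intact(5, cfg); a[3, 10:12] <- 0L
  ev1 <- candidate_from_states(a, intact(5, cfg), cfg)
  sil1 <- reconstruct_silhouette(ev1, list(mean = 30))
  expect_equal(nrow(sil1$occupancy), 1)
  expect_equal(unname(sil1$extent["length"]), 0)

  # undefined velocity -> no silhouette
  expect_null(reconstruct_silhouette(ev, list(mean = NA_real_)))
})

test_that("timestamps are start_time + start_frame / f", {
  cfg <- full_scale_config()
  t0 <- as.POSIXct("2025-06-01 10:00:00", tz = "UTC")
  stream <- beam_stream(cfg, intact(200, cfg), intact(200, cfg),
                        start_time = t0)
  stream$states_a[151:160, 5] <- 0L
  ev <- candidate_event(stream, 150L, 159L)
  expect_equal(as.numeric(assign_timestamp(ev) - t0, units = "secs"), 3)
  ev0 <- candidate_event(stream, 0L, 9L)
  expect_equal(assign_timestamp(ev0), t0)
})

test_that("time reversal flips direction and preserves morphometrics", {
  cfg <- full_scale_config()
  set.seed(404)
  for (i in 1:15) {
    fish <- fish_spec(length = runif(1, 7, 18), height = runif(1, 3, 8),
                      depth_center = runif(1, 15, 40),
                      speed = runif(1, 10, 80),
                      direction = sample(c(-1L, 1L), 1),
                      shape = sample(c("ellipse", "rectangle"), 1),
                      entry_time = runif(1, 0.5, 1.2))
    sim <- simulate_passage(fish, cfg,
                            fish$entry_time + (fish$length + 6) / fish$speed + 1)
    fwd <- classify_stream(sim$stream)$accepted
    rev <- classify_stream(reverse_stream(sim$stream))$accepted
    expect_length(fwd, 1)
    expect_length(rev, 1)
    expect_equal(rev[[1]]$direction, -fwd[[1]]$direction)
    expect_equal(rev[[1]]$direction_estimate$entry,
                 -fwd[[1]]$direction_estimate$exit)
    expect_identical(rev[[1]]$morphometrics$length,
                     fwd[[1]]$morphometrics$length)
    expect_identical(rev[[1]]$morphometrics$height,
                     fwd[[1]]$morphometrics$height)
  }
})
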