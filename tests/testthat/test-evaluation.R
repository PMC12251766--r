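mk_truth <- function(times, tags = "clean", detectable = TRUE) {
  t0 <- as.POSIXct("2025-06-01 10:00:00", tz = "UTC")
  data.frame(time = t0 + times,
             scenario_tag = rep_len(tags, length(times)),
             expected_detectable = rep_len(detectable, length(times)),
             stringsAsFactors = FALSE)
}

mk_det <- function(times) {
  t0 <- as.POSIXct("2025-06-01 10:00:00", tz = "UTC")
  data.frame(timestamp = t0 + times)
}

test_that("greedy timestamp matching splits hits, misses, false positives", {
  m <- match_events(mk_det(c(10, 20, 30)), mk_truth(c(10.5, 19.8, 30.2)))
  expect_equal(nrow(m$hits), 3)
  expect_equal(nrow(m$misses), 0)
  expect_equal(nrow(m$false_positives), 0)

  m <- match_events(mk_det(10), mk_truth(c(10, 50)))
  expect_equal(nrow(m$hits), 1)
  expect_equal(nrow(m$misses), 1)

  m <- match_events(mk_det(c(10, 200)), mk_truth(10))
  expect_equal(nrow(m$hits), 1)
  expect_equal(nrow(m$false_positives), 1)

  # one-to-one: two detections cannot claim the same truth
  m <- match_events(mk_det(c(10, 10.5)), mk_truth(10))
  expect_equal(nrow(m$hits), 1)
  expect_equal(nrow(m$false_positives), 1)

  # unmatched non-detectable truths are reported separately, not as misses
  m <- match_events(mk_det(numeric(0)), mk_truth(c(5, 10), detectable = c(TRUE, FALSE)))
  expect_equal(nrow(m$misses), 1)
  expect_equal(nrow(m$undetectable), 1)
})

test_that("matching is invariant under time translation", {
  det <- mk_det(c(3, 17, 40))
  tru <- mk_truth(c(2.5, 18, 80))
  m0 <- match_events(det, tru)
  det$timestamp <- det$timestamp + 3600
  tru$time <- tru$time + 3600
  m1 <- match_events(det, tru)
  expect_equal(m1$hits[c("det", "tru")], m0$hits[c("det", "tru")])
  expect_equal(nrow(m1$misses), nrow(m0$misses))
  expect_equal(nrow(m1$false_positives), nrow(m0$false_positives))
})

test_that("detection rate is the hit percentage of detectable truths", {
  expect_equal(detection_rate(20, 20), 100)
  expect_equal(detection_rate(19, 20), 95)
  expect_equal(detection_rate(0, 5), 0)
  expect_error(detection_rate(1, 0))
})

test_that("error categorisation yields percentages summing to 100", {
  breakdown <- categorize_errors(c("case_I", "case_I", "case_III"))
  expect_equal(breakdown$percentage[breakdown$category == "case_I"], 200 / 3)
  expect_equal(breakdown$percentage[breakdown$category == "case_III"], 100 / 3)
  expect_equal(sum(breakdown$percentage), 100)

  # the four-way split 16 / 11 / 7 / 1 reproduces the field percentages
  tags <- rep(c("case_I", "case_II", "case_III", "case_IV"), c(16, 11, 7, 1))
  four_way <- categorize_errors(mk_truth(seq_along(tags), tags = tags))
  expect_equal(round(four_way$percentage, 2), c(45.71, 31.43, 20.00, 2.86))
  expect_equal(sum(four_way$percentage), 100)

  expect_equal(nrow(categorize_errors(character(0))), 0)

  # random tag mixes always sum to 100
  set.seed(606)
  for (i in 1:20) {
    tags <- sample(paste0("case_", c("I", "II", "III", "IV")),
                   sample(1:50, 1), replace = TRUE)
    expect_equal(sum(categorize_errors(tags)$percentage), 100,
                 tolerance = 1e-8)
  }
})

test_that("allometric comparison flags bands and recovers exact slopes", {
  # a 5 cm high, 13.75 cm long fish sits inside [2.5H, 3H] = [12.5, 15]
  one <- allometric_compare(data.frame(length = 13.75, height = 5))
  expect_true(one$events$inside_band)
  expect_null(one$fit) # single bin: no regression

  # events generated with L = 2.75 H exactly: fitted slope 2.75
  h <- rep(seq(3, 12, by = 0.5), each = 3) + rep(c(-0.1, 0, 0.1), 19)
  ev <- data.frame(height = h, length = 2.75 * h)
  rep_ <- allometric_compare(ev)
  expect_equal(unname(coef(rep_$fit)[2]), 2.75, tolerance = 1e-8)
  expect_true(all(rep_$events$inside_band))
  expect_true(all(c("height_iqr", "length_iqr", "n") %in% names(rep_$bins)))
})

test_that("allometric slopes survive the measurement pipeline", {
  # noise-free rectangle fish with L = b * H exactly, heights spread over
  # 4-16 cm at random depths; an exact-velocity speed leaves only beam and
  # frame quantization (|height error| <= 0.75 cm, |length error| <= 1.2 cm,
  # near zero-mean within each 1.5 cm bin), so the bin-median regression
  # recovers b well inside 0.2 over the 12 cm height span
  cfg <- full_scale_config()
  set.seed(707)
  heights <- runif(60, 4, 16)
  depths <- runif(60, 20, 35)
  for (b in c(2.5, 2.75, 3.0)) {
    est <- lapply(seq_along(heights), function(i) {
      h <- heights[i]
      fish <- fish_spec(length = b * h, height = h, depth_center = depths[i],
                        speed = 30, shape = "rectangle", entry_time = 1)
      sim <- simulate_passage(fish, cfg, 1 + (b * h + 6) / 30 + 1)
      res <- classify_stream(sim$stream)
      expect_length(res$accepted, 1)
      res$accepted[[1]]$morphometrics
    })
    ev <- data.frame(height = vapply(est, `[[`, 0, "height"),
                     length = vapply(est, `[[`, 0, "length"))
    # the per-event regression is unbiased up to quantization noise:
    # attenuation b * var(e_H)/var(H) (~0.05) plus 3 s.e. of the slope
    raw_slope <- unname(coef(stats::lm(length ~ height, ev))[2])
    expect_lt(abs(raw_slope - b), 0.2)
    # the bin-median regression additionally carries an edge-truncation
    # bias: the outermost bins only see the inward half of their height
    # preimage, displacing their medians by up to half a beam pitch; bound
    # the resulting slope shift in closed form from the bin layout
    rep_ <- allometric_compare(ev)
    slope <- unname(coef(rep_$fit)[2])
    x <- rep_$bins$height_median
    edge_bias <- b * (cfg$beam_spacing / 2) *
      (abs(x[1] - mean(x)) + abs(x[length(x)] - mean(x))) /
      sum((x - mean(x))^2)
    expect_lt(abs(slope - b), edge_bias + 0.1)
  }
})
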