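Package: fishcurtain
Title: Event Detection and Morphometrics for Infrared Beam-Break Fish Counters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for two-array infrared beam-break fish
    counters: reads binary beam-state log streams, segments them into
    candidate passage events, strips spurious interruptions, estimates
    passage direction, swimming velocity, body length and height, and
    reconstructs 2D fish silhouettes from the interruption matrix. Includes
    a physics-based simulator of rigid fish crossing the light curtain
    (with surface-distortion, overlap, and turnaround error scenarios) and
    an evaluation harness that matches detections against ground truth,
    computes detection rates, categorizes misses, and compares estimated
    morphometrics against allometric length-height models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
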