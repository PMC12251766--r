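---
title: "From beam states to fish: the fishcurtain processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From beam states to fish: the fishcurtain processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcurtain)
```

## The measurement model

An infrared curtain counter observes a fish only through the beams it
breaks. Two vertical arrays of `n` beams at pitch `s` (cm), a horizontal
gap `D` (cm) apart, are sampled at `f` Hz; every frame is a pair of binary
vectors (0 = interrupted). All estimation in this package rests on four
consequences of that geometry:

1. **Timing across the gap carries speed.** If a rigid body moves
   perpendicular to the curtain at constant speed `V`, the delay between
   the first interruption of the near and far arrays is exactly `D / V`
   seconds (the body penetrates both arrays by the same distance before
   its growing cross-section reaches the nearest beam line, so the
   penetration offset cancels). The same holds for the last interruptions
   at the tail. Hence two independent estimates `V = D / Δt` per event,
   which we average.
2. **Occupancy duration carries length.** One array is covered by the body
   for `L_chord / V` seconds, where `L_chord` is the longest horizontal
   chord crossing a beam line. For a rectangle this is the body length; for
   an ellipse it is slightly shorter unless a beam passes through the
   midline. Length is estimated as `V̄ · (last − first)/f` per array and
   averaged.
3. **Vertical beam extent carries height.** The body covers the beam lines
   between `j_min` and `j_max`; the raw extent `(j_max − j_min)·s`
   under-reads by up to one pitch (a single covered beam reads zero), so
   half a pitch is added back: `H = (j_max − j_min)·s + s/2`. Lattice
   counting gives the sharp bounds: a body of height `h` covers
   `⌊h/s⌋` or `⌊h/s⌋ + 1` beams depending on its vertical offset, so the
   estimate is one of `(⌊h/s⌋ − 1)·s + s/2` and `⌊h/s⌋·s + s/2`. For the
   6.4 cm replica at 1.5 cm pitch that is 5.25 or 6.75 cm — the estimator
   is unbiased only to within this ±0.75 cm band, and no amount of clean
   data narrows it.
4. **Order of activation carries direction.** Entry direction is the sign
   of the first-activation delay (A before B ⇒ +1), exit direction the
   sign of the last-activation delay. Ties (same frame) are 0; an array
   never touched contributes 0. Mapping of ±1 to "upstream"/"downstream"
   is pure configuration (`upstream_label`), since it depends on how the
   instrument is mounted.

Activation is defined **per array**, not per beam: the first/last frame in
which *any* beam of that array is interrupted. Per-beam matching would be
sensitive to slight vertical drift of the body between the two arrays;
per-array timing is not, and for a rigid horizontal mover the two
definitions coincide.

## The event pipeline

`classify_stream()` chains four stages, each exposed separately:

**Segmentation** (`segment_events`). Frames with any broken beam are
"active"; maximal active runs become candidates, runs separated by at most
`gap_frames` intact frames are merged, and candidates with fewer than
`min_active_frames` active frames are dropped. `gap_frames = 5` (0.1 s at
50 Hz) bridges momentary full clearances inside one passage — e.g. a thin
caudal peduncle letting all beams close for a few frames — while keeping
genuinely separate fish apart; `min_active_frames = 2` because a
single-frame event cannot yield a delay, hence neither direction nor
velocity.

**Noise removal** (`remove_random_lines`). Environmental noise appears as
small isolated blobs of interrupted cells. A 4-connected component (per
array, in the frame × beam grid) is reset to intact when it spans at most
`max_width_frames = 2` frames and `max_height_beams = 1` beam *and* the
other array shows no interruption nearby — within `cross_tol_frames = 5`
frames and `cross_beam_tol = 3` beams. The vertical proximity condition is
deliberate: a real object crosses both arrays at nearly the same height,
whereas independent flickers land on uncorrelated beams. Without it,
coincidental flicker pairs on the two arrays pass the cross-array test and
can survive into accepted events. 4-connectivity (diagonal contacts are
separate blobs) keeps the grouping deterministic and conservative. The
operation only removes interruptions, re-trims the event bounds, and is
idempotent; an emptied event is dropped.

**Estimation** (`estimate_directions`, `estimate_velocities`,
`estimate_length`, `estimate_height`, `reconstruct_silhouette`,
`assign_timestamp`). Undefined quantities propagate as `NA` — a zero-frame
delay yields an undefined velocity, never a clamped or infinite one — and
are dealt with by the filter rather than patched. Height uses the union of
both arrays' interrupted beams (the per-array values differ only by
sampling phase; the union maximises vertical evidence). Length uses the
*mean* velocity rather than the entry or exit estimate: the mean halves
the frame-quantization error, and for a symmetric crossing the choice is
immaterial. Occupancy duration is `(last − first)/f`, not `count/f`, which
avoids the +1-frame bias of inclusive counting. Silhouettes are drawn from
array A (falling back to B) at `Δx = V̄/f` per column, column order
reversed for −1 travel so the nose is always drawn first.

**Filtering** (`filter_events`). Three criteria in a fixed order, the
first failure becoming the rejection reason: (1) directionality — entry
plus exit must be non-zero, so turnarounds and symmetric (stationary)
events are rejected; a one-sided tie such as entry +1 / exit 0 sums to +1
and passes; (2) velocity — the mean must be defined and positive (an
optional `max_velocity` cap exists but is off by default, as no principled
upper bound is claimed); (3) height — at least `height_filter_threshold`
(default 1.5 cm, the plausibility floor for a fish body). The final
direction of an accepted event is `sign(entry + exit)`.

## The simulator: what it emulates, and what it does not

`simulate_passage()` moves a rigid 2D silhouette — ellipse or rectangle of
given length and height — horizontally at constant speed through two
point-sampled beam lines at `x = 0` and `x = D`. A beam is interrupted
exactly when the closed body region covers the beam's point; the closed
boundary convention makes edge cases (a body exactly touching a beam)
deterministic. This mirrors the instrument's own idealisation: fish
crossing perpendicular to the curtain at constant speed.

Scenario composition (`simulate_scenario`) superimposes passages (beam
interruptions OR together), an optional surface-distortion band (the top
`k` beams held interrupted for a period, on both arrays — an abstraction
of the water-surface artifacts seen with partially submerged units; the
true vertical extent and duration of such artifacts is not something the
desk model can claim, so both are parameters, not defaults to trust), and
Poisson-timed single-frame single-beam flickers with a mandatory seed.
`scenario_preset()` encodes the canonical failure modes: a masked single
crossing (case I), a second fish swallowed by the band of the first
(case II, marked not-detectable in ground truth since its own signal is
entirely absorbed), two overlapping fish at different depths (case III),
and a turnaround that enters, pokes through the far array, and retreats
(case IV). The replica geometry used throughout — 16.5 cm × 6.4 cm, with a
13.0 cm smaller sibling, at 30 cm/s — matches the physical dummy-fish
protocol the instrument class is validated with; `simulate_dummy_trial()`
reproduces that protocol (10 passages per direction, vertically centred,
deterministic sub-frame phase spread).

What the simulator does **not** emulate: swimming kinematics (undulation,
variable speed, oblique headings), hydrodynamic artifacts (bubbles,
turbulence), partial transparency of fins, or multi-fish social behaviour.
Passing tests therefore demonstrate that the *processing chain* is correct
under the instrument's own assumptions — not that a deployed unit achieves
any particular field accuracy, which depends on exactly the effects left
out. The clean-passage detection rate of 100% in the acceptance checks is
the expected desk-scale result; field rates are lower for physical reasons
the simulator's error scenarios only sketch qualitatively.

## Evaluation choices

Detections are matched to ground truth greedily by nearest timestamp
within a 2 s tolerance (events are several seconds long; the truth
timestamp is nose-at-first-array, the detection timestamp the first active
frame, so sub-second agreement is typical and 2 s is generous without
risking cross-matching of passages spaced 5 s apart). Unmatched truths
split into *misses* (marked detectable) and a separate not-detectable
remainder; unmatched detections are false positives. Miss percentages per
error category sum to 100 by construction.

The allometric comparison bins events by estimated height (1.5 cm bins,
one beam pitch — finer bins would be empty between lattice values of the
height estimator) and fits a least-squares line to the bin medians with
per-bin IQRs. Two caveats are inherent and worth knowing: regression on a
noisily measured height attenuates the slope by roughly
`var(e_H)/var(H)` (about 2% for heights spread over 12 cm), and the
outermost bins see only the inward half of their height preimage, biasing
the bin-median slope toward zero by an amount computable from the bin
layout. The tests assert recovery of `b ∈ {2.5, 2.75, 3.0}` within bounds
derived from exactly these two effects.

## Files, degenerate inputs, and determinism

The log dialect (one header line with the geometry and ISO-8601 start
time; one line per frame with the frame index and the two fixed-width
binary blocks) is defined by this package so that round-trips are
bit-exact and files remain human-inspectable; event clips reuse the same
dialect and are themselves valid logs. Malformed lines fail with the line
number. Hourly operation is modelled as "process any closed log file" —
scheduling is deployment glue, not method. The calibration check flags any
beam intact in less than 99% of a fish-free window; the goal (find stuck
or flickering beams) fixes the shape of the check, and 99% over a
multi-second window separates a healthy beam from any plausible fault
without tripping on a single glitched frame.

Degenerate inputs are handled by explicit convention: an empty stream
yields no candidates; an all-intact stream yields no events; a
single-frame event yields a one-column silhouette of zero length extent;
a fish outside the vertical span yields a silent stream whose truth record
is marked not detectable; `min_guaranteed_height` rejects requests for
more beams than the array has.

Determinism is treated as a feature under test: identical configuration
and seed produce byte-identical logs and event files, and every stochastic
component (flicker noise, test populations) takes an explicit seed.

## Problem sizes

The test and acceptance workloads are sized for seconds, not minutes, by
choice: segmentation is cross-checked against a brute-force run-length
oracle on 1000 random activity strings; velocity/direction recovery on a
few dozen simulated passages spanning 5–100 cm/s; the detection-limit
sweeps use 0.01 cm offset resolution (heights) and 0.25 cm length steps at
2 cm/s (contiguity); the benchmark trial uses 20 passages of the larger
replica; allometric recovery uses 40–60 fish per proportionality. These
sizes put every quantization effect on display while keeping the whole
suite under half a minute.

## Known limitations

Oblique or variable-speed crossings violate the constant-velocity
assumption and would bias length directly; overlapping fish merge into one
candidate (resolving them is out of scope, as is species identification);
the height estimator's ±half-pitch band is irreducible at a given beam
pitch; and the noise-removal rule is geometric, so drifting debris that is
large, slow and cross-array-consistent will pass the filters — as it does
for the instrument class this package models.
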