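---
title: "Measuring larval locomotion: models, parameters and design choices"
author: "larvatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring larval locomotion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

# The measurement problem

A crawling *Drosophila* larva alternates between two modes. While
*striding* it performs peristalsis: the body extends and contracts
rhythmically, and each cycle advances the animal roughly one step; body
length oscillates with a period of about 1.6 s in wild-type third
instars, and the head and tail advance during the extension and
contraction phases respectively. While *non-striding* it pauses, sweeps
its head sideways and bends, traveling very little. A single-animal
tracker records one larva at high magnification, moving a motorized
stage to keep it centered, and logs the stage position over time.

`larvatrack` turns such a recording — frames plus stage log — into a
13-point midline per frame and a panel of 21 per-video parameters
covering shape (body length and bending), peristalsis (speed, striding
time, stride duration/distance, contraction and extension rates),
stamina (stride and run counts, run statistics) and track geometry
(distance, direction changes, time away from the arena's confinement
ring).

# Midline extraction

Each frame is assumed to show one dark larva on a light background
(high-contrast imaging). Processing per frame:

1. **Binarization.** Otsu's threshold, computed per frame (a fixed
   override is available via `run_config(threshold = )`). Only the
   largest connected component is kept, interior holes are filled, and
   the component area must fall within `min_area`–`max_area`
   (0.5–20 mm²); otherwise the frame is invalid. These bounds reject
   empty frames and gross segmentation failures rather than tuning the
   result.
2. **Skeletonization.** Zhang–Suen thinning produces a one-pixel
   topological skeleton. Side branches (width artifacts) are pruned
   iteratively: while more than two endpoints remain, the shortest
   endpoint-to-junction branch is removed, provided it is shorter than
   `prune_frac` (15%) of the skeleton — long enough to exceed half the
   body width, short enough never to truncate the head. A skeleton that
   cannot be reduced to two endpoints (a looped, self-touching posture)
   invalidates the frame with reason `"topology"`; curled animals are
   out of scope by design.
3. **End extension.** Thinning erodes the skeleton ends by roughly half
   the body width. Both ends are therefore extended along their local
   tangent until they leave the silhouette. Correspondingly, the
   bundled renderer draws the body as a capsule over a midline trimmed
   by half the width at each end, so silhouette extent equals true
   midline length and the round trip is unbiased. Without the
   extension, body length would read ~15% short.
4. **De-jagging and resampling.** The ordered pixel chain is smoothed
   with a 5-px moving average (endpoints pinned) — an 8-connected
   staircase otherwise inflates arc length by up to 8% for diagonal
   postures — then divided into 12 arc-length-equal segments whose
   13 endpoints form the midline, head first after orientation.
5. **Plate mapping.** `plate = stage + S * (pixel - image_center) *
   mm_per_pixel`, with `S` one of the four axis-aligned sign mappings
   (default flips y: image y runs down, plate y up). Missing stage
   entries are carried forward for gaps of at most 2 frames; longer
   gaps invalidate frames with reason `"stage_gap"`.

**Head/tail orientation** is not derivable from a single silhouette.
Two passes are used: endpoint labels are first made temporally
continuous (each frame keeps the ordering that minimizes frame-to-frame
endpoint displacement), then the whole series is flipped, if necessary,
so the head endpoint has the larger mean instantaneous speed — true in
both modes, since the head leads extension while striding and sweeps
while pausing. The `orientation_confidence` attribute reports the
speed-ratio margin `(v_head - v_tail)/(v_head + v_tail)`; a single-frame
series gets confidence 0 and an arbitrary orientation. This heuristic is
a reconstruction — established trackers disambiguate head from tail in
various ways — and downstream head-angle statistics should be read with
that in mind.

Invalid frames propagate as gaps: no statistic interpolates across
them, strides straddling them are dropped, and a video with more than
20% invalid frames is flagged in its summary.

# Per-frame measures

*Body length* is the sum of the 12 inter-point distances. *Point speed*
is a centered displacement quotient over a `speed_window` of 0.5 s
(≈ 4 frames at 7.5 fps): long enough to suppress pixel jitter, short
enough (well under one stride period) to preserve the within-cycle
head/tail speed alternation. *Head angle* is the angle between the head
chord (point 3 → 1) and the anterior body chord (point 7 → 3); *body
angle* is the deviation from straight at the center, 180° minus the
interior angle at point 7 between the chords to points 1 and 13. Both
are unsigned in [0°, 180°]; chord-based angles on points {1, 3, 7, 13}
are the simplest scheme that separates a head bend from a body bend,
and the exact indices are a design choice — validation relies on
synthetic geometry with known bend angles, not on matching any
particular legacy tool. A frame is *bending* when either angle strictly
exceeds 45°.

# Stride detection

The body-length signal is smoothed with a 0.4-s moving average and its
local extrema are filtered by topographic prominence
(`min_prominence_frac` = 3% of mean body length — about half the
smallest plausible stride amplitude, and far above recognizer noise).
Consecutive same-type extrema are resolved by keeping the more extreme
one, so minima and maxima strictly alternate; extremum *values* are
read from the raw signal at the detected positions.

A minimum-to-minimum interval is an accepted stride when:

* its duration lies within `period_min`–`period_max` (0.4–5 s, bounds
  that bracket observed wild-type stride durations generously),
* its length excursion reaches the prominence threshold, and
* the body center advances at least `min_stride_displacement` (0.1 mm)
  — rhythmic length change without travel (bending in place) is not
  peristalsis.

Frames inside accepted strides are *striding*; everything else is
non-striding. Strides whose gap is at most `max_gap` (0.5 s) merge into
*runs*. Contraction and extension rates are the slope of a linear fit
over the interior of each phase (25% trimmed at both ends): identical
to the endpoint difference quotient for a linear phase, but immune to
the ±1-frame extremum localization error that biases the quotient by
~15% at 7.5 fps. An optional head/tail speed-symmetry criterion for
striding (`require_speed_symmetry`) exists but is off by default; the
published descriptions of peristalsis mention the symmetry, and it is
unclear whether any original implementation enforced it.

Body Length Contracted / Extended are means over the per-stride length
minima / maxima, and are reported as missing — never zero — when a
video has no strides, as are all other stride-derived parameters.

# Track measures

The center-point track is smoothed (0.5-s moving average with odd-
reflection padding, which passes linear motion through unchanged) before
summing displacements into total distance; an unsmoothed sum is biased
upward by noise. *Direction changes* subsample the track at 1-s
intervals and flag interior samples whose turning angle exceeds 60°;
the fraction of flagged samples is reported. Both constants are
conventions — no published value fixes them — and are config-exposed.
*Time inside* partitions frames by radial distance: a frame is inside
when the center is more than `inside_margin` (default half a body
length, the natural reading of "close to" the ring) from the ring's
inner edge, i.e. within 35 mm minus the margin of the plate center for
a 10-cm dish with a 1.5-cm ring.

Parameters defined per frame or per stride additionally get
inside/outside variants by masking frames (strides are assigned by
majority of their frames) before averaging.

# Aggregation and normalization

Per-frame parameters are averaged over valid frames (striding-only
subsets where the parameter exists only during strides); per-video
parameters are computed once. "Speed" averages per-frame center speeds
by default; dividing total displacement by total time is available as
`speed_mode = "total"` since either reading of a per-video mean speed
is defensible. Stride Count and Run Count are normalized to counts/min;
raw totals are also exported. The coefficient of variation is
`100 * sd / mean` with the sample (n−1) SD, undefined for n < 2 or zero
mean.

Day-to-day variation is cancelled by same-day-control normalization:
each animal's values are divided by the mean of control animals tracked
on the same date (an explicit `date` metadata column — never parsed
from filenames — keys the match). Scaling all same-date raw values by
any positive constant leaves normalized values unchanged, which is
exactly the failure mode (shared day effects) the procedure removes.
Genotype-by-parameter matrices of normalized means or normalized SDs
form phenotypic profiles; Pearson correlation between profile rows
quantifies phenotypic similarity. Inferential statistics are out of
scope: the summary tables are designed for direct import into standard
statistical tools.

# The synthetic crawler

All validation is recovery of known truth from a generative model, so
what the generator does and does not emulate bounds what the tests
show.

**Striding.** Body length follows a piecewise-linear cycle between
`mean_length ± length_amplitude` with period `stride_period`; the
extension phase occupies `extension_fraction` of the cycle (default
0.5; values below 0.5 reproduce the faster extension seen in real
animals, and the asymmetry exercises the phase-splitting of the stride
engine). The center advances `stride_distance` per cycle at constant
speed; heading drifts by N(0, `run_turn_sd`) per stride and reflects
off the confinement ring. Rotations act about the body center, so
steering adds no spurious center displacement.

**Pauses.** Bout durations are exponential (the minimal memoryless
choice; no published bout-length model exists), scheduled to hit
`time_striding_target` and `n_runs_target` with an integer number of
strides per run, so stride boundaries nest exactly inside run
boundaries. During a pause the center is fixed; length relaxes toward
the mean between short stationary flats at the contracted length
adjacent to strides (the animal settles before initiating a stride),
and the head sweeps sinusoidally up to `head_sweep_amplitude` with a
4-s period. Defaults are anchored to wild-type values: length 4.34 mm,
amplitude 0.255 mm (half the contracted-to-extended span), period
1.61 s, stride distance 0.89 mm, striding fraction 0.76, 9 runs per
4-minute session, 7.5 frames/s, a 50-mm plate with a 15-mm ring.

**Rendering.** The worm is drawn as a 0.8-mm-wide dark capsule on
white, 240×240 px at 0.05 mm/px; a virtual stage re-centers whenever
the centroid leaves the central third of the frame and is logged per
frame, exactly inverting the recognizer's plate mapping.

**Not emulated:** segmental anatomy (denticle bands), self-occluding or
rolled postures, backward crawling, illumination gradients, camera blur
and real sensor noise, multi-animal scenes. Passing recovery tests
therefore demonstrates the correctness of the measurement chain on
clean single-animal geometry, not robustness to degraded imaging.

# Numerical choices and degenerate inputs

* Pixel centers sit at integer coordinates, image origin top-left;
  plate frame is mm, x right, y up; times are seconds from the first
  frame. The points file format fixes these conventions for
  interchange.
* Arc-length resampling interpolates linearly along the pixel path and
  preserves endpoints exactly; equal spacing holds to within ~4% after
  rendering and recognition (tolerance 10% in the pose invariant).
* A pose with a segment below 10% of the median segment length still
  has a defined body length; zero-length chords make bend angles
  undefined for that frame rather than erroring.
* Plateaus in the length signal take their extremum at the plateau
  midpoint; boundary extrema are not detected (a cycle must be
  complete to count).
* Validation problem sizes: round-trip tests run 10–30-s sessions;
  the full-session check and the acceptance script use one 240-s,
  1800-frame session plus twenty 180-s analysis-only replicates with
  parameters drawn across the plausible crawler range (periods
  0.8–3 s, stride distances 0.5–1.3 mm, striding fractions 0.4–0.95).

# Known limitations

* The recognized head angle under-reads sharp bends (corner rounding by
  the skeleton smoothing): a 70° true sweep reads ≈ 50°. The 45°
  bending threshold is applied to the recognized angle, so bending-time
  parameters are conservative on real video; amplitude-accuracy tests
  use generator truth.
* Stride durations of boundary strides (first and last of a run)
  extend into the adjacent pause by up to the settling flat, biasing
  mean stride duration upward by a few percent in heavily fragmented
  sessions.
* The speed-based head/tail heuristic can fail for an animal that is
  nearly stationary throughout; `orientation_confidence` near zero
  marks such videos.
* Backward crawling is not modeled or detected; the rare backward
  stride would be measured as a forward one.
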