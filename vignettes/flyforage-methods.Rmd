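---
title: "Methods: trajectory segmentation, patch events and foraging parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory segmentation, patch events and foraging parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyforage)
```

# The measurement model

A single fly walks for up to two hours in a flat circular arena
(inner radius 25 mm) containing 18 food patches — 9 yeast, 9 sucrose,
radius ≈ 1.5 mm — tracked from above at 50 frames/s. The tracker yields
per-frame body and head centroids (and either a tail centroid or
unlabeled body-axis endpoints), in pixels (0.155 mm/px) or mm. All
downstream quantities are *head-centric*: feeding is proxied by slow
head movement close to a patch center, because proboscis contact cannot
be resolved from above.

The analysis assumes: (i) the arena frame is fixed (positions are
arena-centered mm); (ii) patch centers are at least 10 mm apart, so a
head can be within the 2.5 mm feeding radius of at most one patch;
(iii) frame loss is modest — flies with more than 10% lost frames are
excluded, shorter gaps are linearly interpolated before smoothing (the
gap mask is retained; we interpolate long gaps too rather than
splitting the track, because every event rule is a function of contiguous
frame indices — a documented simplification).

# Kinematic channels

Raw positions are smoothed with a Gaussian kernel of **0.32 s total
support** (16 frames). "Width" is read as total kernel support, with
σ = width/6 and the kernel truncated to that support and renormalized;
this makes the stated frame counts literal, and a 6σ support carries
> 99.7% of the mass so the truncation is cosmetic. At track ends the
kernel is renormalized over the available samples, so constant tracks
are exact fixed points and there are no padding artifacts.

Speed is the forward difference of smoothed positions times the frame
rate, with the last frame replicating the penultimate value so channels
stay full-length. Heading is the direction of the head-minus-tail
vector of the smoothed centroids; angular speed is the shortest-arc
heading difference times the frame rate, signed, in (−180°, 180°] × 50/s.
Coincident head and tail (a degenerate frame) carries the previous
heading forward.

Two extra-filtered head-speed channels drive classification: a 1.2 s
filter for the walk threshold and a 2.4 s filter for the rest
threshold, both applied to the speed channel (not the positions). The
wider rest filter prevents flicker around the tiny 0.2 mm/s threshold.

When the tracker supplies unlabeled axis endpoints, head identity is
propagated by frame-to-frame proximity within each inter-jump interval
and then the interval's labeling is kept or globally flipped to
maximize agreement between the body axis and the displacement direction
(flies walk forward most of the time). Jumps are detected as
frame-to-frame body displacement above 5 mm (roughly 1.5 body lengths
in one frame); the threshold is configurable because the underlying
assay defines jumps only operationally. Intervals with near-zero net
displacement keep the proximity labeling and are flagged low-confidence.
When only head and body are given, the tail is reconstructed as the
head reflected through the body and flagged in metadata.

# Ethogram

Per-frame labels partition the track:

| label | rule | channel |
|---|---|---|
| walk | filtered head speed > 2 mm/s | 1.2 s channel |
| rest | non-walk and filtered head speed ≤ 0.2 mm/s | 2.4 s channel |
| micromovement | remaining non-walk frames | — |

Walk takes precedence when the two filtered channels disagree, because
rest is only defined *within non-walking segments*. A constant speed of
exactly 2 mm/s is a micromovement (the class bounds are
0.2 < v ≤ 2 mm/s).

Sharp turns are an *overlay*, not a fourth exclusive label, keeping the
partition invariant clean. An event anchors at a strict local maximum
of |angular speed| above 125 °/s whose body speed is below 4 mm/s. The
event extent grows from the peak until |angular speed| falls below half
the threshold, and overlapping extents merge — the half-threshold
hysteresis is our choice (the extent rule is not specified by the
assay) and is config-exposed. A 2 mm/s *lower* body-speed bound appears
in the assay's figure description but not its operational definition;
the default follows the operational definition (no lower bound) and the
bound is available as a configuration switch.

# Patch events

All distance rules test the smoothed head against patch centers; the
patch radius itself is never an event threshold. Intervals are
half-open `[start, end)` in frames, so durations are `(end − start)/fps`
and bout tables tile the track unambiguously.

* **Encounter**: maximal run of frames with head ≤ 3 mm from a center.
  Consecutive same-patch encounters merge when (a) during the gap the
  head never strays more than 0.31 mm (2 px) from its position at the
  start of the gap, or (b) the head never exceeds 5 mm from that center
  during the gap. The "total displacement ≤ 2 px" phrase is ambiguous;
  we implement the strictest reading — maximum excursion from the gap's
  first head position — and expose it in configuration. Merging runs to
  a fixpoint and never crosses patches.
* **Food micromovement**: run of frames labeled micromovement with head
  ≤ 2.5 mm from a center, same-patch interruptions merged under the
  2 px rule only. A micromovement at 2.6 mm is not a food
  micromovement, but it can still sit inside an encounter.
* **Visit**: consecutive same-patch food micromovements whose gaps keep
  the head within 5 mm of the center. The visit spans the first
  micromovement's start to the last one's end; per-visit summaries
  record the minimum head-to-center distance and the number of distinct
  0.155 mm grid cells (arena-origin aligned, so areas are comparable
  across flies) covered by the head over the whole span.

These definitions give the containment laws the test suite asserts:
every visit lies inside an encounter of the same patch, visit time
dominates contained micromovement time, and an encounter without a food
micromovement is a rejected patch (the fly did not stop).

# Per-fly parameters

The parameter set is computed per fly over the whole assay unless
windowed. Decisions worth recording:

* **P(stop)** divides stopped encounters (those containing ≥ 1 food
  micromovement of the same patch) by all encounters; with zero
  encounters it is *missing*, never zero. All undefined ratios
  propagate as `NA` and are excluded pairwise from group statistics.
* **Encounter rate** divides by minutes spent *walking* with the head
  more than 2.5 mm from every patch center.
* **Rolling exploitation curve** is named a "rolling median" in the
  assay but defined as a windowed *sum* of visit durations (5 min
  window, 4 min step); we implement the per-fly windowed sum and take
  medians across flies for plots. Visits crossing a window boundary
  contribute their overlap to each window (clipping keeps the series
  conservative and interpretable).
* **Transitions** classify consecutive yeast-visit pairs: *same* patch
  with head ≤ 16 mm from it throughout the gap; *adjacent* when the
  patches differ, centers ≤ 16 mm and the head stayed ≤ 16 mm from the
  previous center; *distant* otherwise. Intervening sucrose visits do
  not break a yeast-to-yeast transition (config switch). Probabilities
  divide class counts by the number of *transitions* (one fewer than
  visits), which is what makes them sum to one; the assay's text
  divides by visit counts, leaving the first visit's mass unassigned —
  we prefer the normalized version and provide the pie-chart helper
  that rescales across-fly medians to 100%.
* **Yeast quartiles** anchor at the latency point (start of the first
  ≥ 30 s yeast visit; censored at assay end when none exists). The
  cumulative yeast-micromovement time from there is 100%; boundaries
  fall after the `round(k·T/4)`-th yeast frame, so each window holds
  25% ± 1 frame and the windows are contiguous in absolute time.
  Windowed metrics attribute visits by their start frame and
  transitions by the start of the destination visit.

# Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test (exact when
tie-free and small, normal approximation otherwise) with Bonferroni
correction — the family size is the number of planned comparisons
passed in, mirroring each figure's comparison set. The 2×2 test pairs
Fisher's exact p with *modified-Wald* (add-2 Agresti–Coull) confidence
intervals for the per-group proportions; these are two distinct
procedures reported side by side rather than a guessed hybrid. The
bootstrap for median differences resamples flies with replacement
within each group (10,000 replicates by default, documented seed) and
reports 5%/95% percentile bounds; non-overlap of two such intervals is
the significance criterion used for median-difference bar plots.

# The synthetic forager

No generative model is specified by the assay; the simulator is a
stand-in whose purpose is to make every pipeline stage testable against
ground truth. It is a semi-Markov bout process:

* **Movement.** Walking legs are straight-with-curvature segments at
  ~10 mm/s toward a target, detouring around non-target patches;
  on-patch micromovement is a correlated random walk at ~0.8 mm/s
  confined within 2 mm of the center; rest is sub-thresholds jitter.
  Sharp pivots (body pinned, head sweeping 90–180° at 160–300 °/s) are
  injected before transits so the sharp-turn detector has true
  positives. The head leads the body by 1.25 mm along the heading;
  tail mirrors it. Speeds were chosen so the *smoothed* channels land
  in the classifier's three bands.
* **Decisions.** The next target is the just-left patch with
  probability `revisit_bias`, otherwise a patch drawn with weight
  exp(−distance/`local_range`). On crossing 3 mm the fly stops with
  probability `p_stop_<substrate>`; a visit's duration is exponential
  with hazard `leave_rate` (minimum 2 s so every intended visit is
  detectable after filter transients); departures move 6–9 mm away
  before the next decision, which keeps consecutive events distinct
  under the 5 mm merge rule.
* **Ground truth** logs intent — target patch, stop decision, visit
  span, per-frame activity — so detector evaluation is label-based.

The five presets (`virgin_rich` … `mated_deprived`) are documented
constants ordered so exploitation rises and global exploration falls
with mating and amino-acid challenge: stop probability 0.20 → 0.80,
leaving hazard 0.25 → 0.05 s⁻¹, revisit bias 0.02 → 0.40, targeting
range 40 → 6 mm, on-patch activity 0.60 → 0.90. Sucrose stopping
*falls* with challenge (0.50 → 0.15): the homeostatic compensation is
yeast-specific, and without it intervening sucrose visits dilute the
yeast-to-yeast transition structure. No claim is made that preset
magnitudes match the published medians — only the qualitative orderings
asserted in the acceptance tests.

What the generator does **not** emulate: tracker noise and lost frames
(clean tracks by construction; QC is tested separately), grooming
vs feeding structure inside micromovements, patch depletion,
arena-edge thigmotaxis, and any fitted correspondence to the deposited
raw data. A green test therefore establishes that the pipeline
implements its stated rules and recovers known generative parameters —
not that it reproduces the published numbers, which would require the
archived tracking data.

One estimator note: the acceptance check of preset transition orderings
pools transitions across the cohort before forming class fractions.
Per-fly probability medians with ~30 transitions per fly are too noisy
to order probabilities around 0.1 at desk-scale cohort sizes; the
pooled fraction estimates the same population quantity with far less
variance.

# Numerical and degenerate-input choices

* Frames are 1-based internally; exported tables are 0-based like the
  tracker's output.
* Kernel supports of even frame counts use the centered odd grid
  (17 taps for 16 frames) to avoid a half-frame phase shift.
* `arena()` validates geometry at construction; the standard builder
  places 12 patches at 22 mm and 6 at 12.5 mm radius (the split is not
  dictated by the assay — these radii satisfy every printed constraint:
  ≥ 10 mm spacing, both-substrate adjacency within 16 mm, centers
  inside 25 mm). The `seed` argument only rotates the layout.
* Zero encounters/visits/transitions yield `NA` aggregates; the
  latency is censored at assay duration; quartiles are undefined for
  censored flies.
* Bootstrap and simulation are deterministic given their seed;
  `run_pipeline` outputs are byte-stable and stamped with a config
  hash.

# Known limitations

* The event oracle equivalence is demonstrated on synthetic channel
  tracks; real tracker artifacts (identity swaps at jumps, blob
  merges near the wall) are out of scope beyond the head/tail
  disambiguation rule.
* The rolling-curve and quartile figures summarize across flies; this
  package returns per-fly series and leaves figure assembly to the
  caller.
* flyPAD sip-level feeding microstructure is a different instrument and
  is deliberately not implemented.
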