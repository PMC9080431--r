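---
title: "Validating detector-based fish tracking and scoring behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating detector-based fish tracking and scoring behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arenatrack)
```

## The problem

A single fish is recorded in an experimental arena at one analysed frame
per second. A trained object detector emits, per frame, the classification
probability of its single most reliable proposal and a bounding box. Two
derived signals carry all downstream analysis:

* **presence/absence** — the probability thresholded at τ. The shelter
  hides the fish from the camera, so a detection is equivalent to "outside
  the shelter";
* **position** — the centroid of the bounding box.

Before behavioural conclusions can rest on these signals, both must be
validated against human scoring, and the validation statistics must be
computed under explicit, reproducible conventions. `arenatrack` implements
that validation and the behavioural metrics, and pairs them with a
synthetic-arena generator whose parameters are known exactly, so that every
stage of the pipeline can be checked by parameter recovery rather than by
eye.

## Validation conventions

**Threshold rule.** A frame is predicted present when *p* ≥ τ. The
inclusive boundary makes τ = 0.5 symmetric for a score sitting exactly at
0.5; the comparison is exposed in `validation_config()` rather than buried.

**Matching split.** Per video, the matching percentage is computed overall
and separately over the manually-present and manually-absent frames. The
overall value always equals the frame-weighted mean of the two parts; a
part with no frames is reported as missing, never as 0 or 100. The split
matters because the two error channels differ in kind: a missed visible
fish (score below τ) versus a phantom detection while the fish is hidden —
in practice often the novel object mistaken for a fish.

**Aggregation.** Videos are the experimental unit: each contributes one
overall percentage to the cross-video mean regardless of its length. The
confidence interval is the normal approximation mean ± z·SD/√n with
z = 1.96. This convention reproduces the worked examples it was checked
against exactly at two decimals (e.g. `ci_of_mean(92.79, 6.78, 14)` →
89.24–96.34); a Student-t interval does not.

**RMSE.** Two definitions are plausible and both are implemented:
`frame_pooled` (default), 100·√(pooled mismatch fraction over all frames),
and `per_video`, the root mean square of per-video error percentages. For
published summary tables of this kind the RMSE definition is typically not
recoverable from the printed means and SDs, and neither definition here
claims to match any particular published value; the mode is recorded in the
output manifest.

**Positioning.** The error is the Euclidean distance between predicted and
manual box centroids. The success threshold is the mean over the pooled
side lengths of all manual boxes — each box contributes its width and its
height once (`per_box_mean` is available; the two differ only under
unbalanced aspect ratios). Success is inclusive (e ≤ threshold). The
summary reports mean, sample SD (n−1), the same CI convention, and
RMSE = √(mean e²); the identity RMSE² = mean² + population variance is
asserted in the test suite on every run. Validation frames are apportioned
across videos proportionally to fish-present time by largest remainder
(floors first, leftover units to the largest fractional remainders, ties to
the earlier video), then drawn uniformly without replacement.

## The synthetic arena

The generator stands in for the unreleased recordings and defines the
study conditions used throughout the tests and the acceptance script.

**Occupancy.** A two-state Markov chain over hidden/visible with per-step
exit and entry probabilities. Defaults `p_exit = p_enter = 0.02` give mean
bout lengths of 50 s and a stationary visible fraction of 0.5 — a fish that
uses its shelter heavily but emerges regularly, which is the regime in
which both parts of the matching split are well populated. The stationary
visible fraction is `p_exit/(p_exit + p_enter)`; bout lengths are geometric
with means `1/p_enter` (visible) and `1/p_exit` (hidden).

**Movement.** A correlated random walk: the heading is a
persistence-weighted blend of the previous heading and a fresh uniform
direction (`persistence = 0.7`), the step length is |N(0, 20 px)|, and each
visible bout re-emerges at the shelter anchor. Positions reflect at the
borders of an inset rectangle (below). No published movement model exists
for this assay; these values produce paths that cover a realistic fraction
of the arena within an hour without pinning to a wall, and they are free
scenario settings, not estimates of any species' behaviour.

**Detector scores.** Beta laws conditioned on the true state:
Beta(8, 2) when visible, Beta(2, 8) when hidden. A bounded, skewed score
law is the natural model for a classifier's confidence, and it makes
threshold-dependent error rates analytically available: the miss rate at τ
is the Beta CDF F₁(τ) and the false-positive rate is 1 − F₀(τ). At τ = 0.5
both expected part-wise matching percentages are 98.05 %, which the sweep
recovers within binomial error. A degenerate point-mass option
(probability exactly 1/0) exists for noiseless exact tests.

**Centroid noise.** Per-axis Gaussian jitter plus a relocation mixture:
with probability `outlier_prob` (and on every hidden frame) the emitted box
is placed uniformly in the arena or onto the novel object. The defaults
σ = 5 px, outlier probability 0.01 were chosen analytically, before any
testing, to reproduce the characteristic small-mean / large-SD structure of
detector positioning error: the non-outlier error is Rayleigh(σ) with mean
σ√(π/2) ≈ 6.3 px, while the relocation term contributes ≈ p·E[d²] ≈
0.01·3.7·10⁵ px² to the second moment, predicting a mean near 10 px, an SD
near 60 px and an RMSE near 62 px. The acceptance run at the default seed
measures 13.5 / 78.8 / 79.9 px on 1,085 sampled frames — same structure,
with the wide spread expected when a heavy tail is estimated from ~11
outliers.

## Numerical choices

* **Sub-pixel lattice.** True positions are quantised to 1/16 px. Detectors
  emit integer-pixel boxes, so this is finer than any real signal; its
  purpose is numerical: lattice coordinates make box construction
  (x ± half-width) and centroid recovery exact in double precision, so the
  noiseless limit reproduces ground truth bit for bit instead of to 1 ulp.
* **Border margin.** The path reflects inside an inset rectangle whose
  default margin is the box half-extent plus four jitter SDs. A real fish's
  centroid cannot reach the wall (the body has extent), and the margin
  guarantees that emitted boxes essentially never need clipping. Without
  it, the reflected walk lingers near walls (~15 % of frames in the default
  scenario) and clipping systematically truncates the jitter there, biasing
  error moments low by ≈ 1.4 %.
* **RNG sub-streams.** Each stage (occupancy, path, detections, frame
  sampling) seeds its own stream derived deterministically from the base
  seed, so re-running or adding one stage never shifts another's draws;
  identical parameters and seed give byte-identical output files.
* **Grid boundary rule.** Area coverage assigns a point on a cell boundary
  to the larger-index cell; points on the far arena border fold into the
  last cell, so the 1280 × 768 arena at 32 px is exactly 40 × 24 = 960
  cells.
* **Undefined values.** A turning angle with no valid triplet (fewer than
  three consecutive present frames with two non-zero displacements) and a
  minimum object distance with no present frame are `NA`, never 0; zero
  displacements are skipped, not averaged in as zero angles.
* **Alignment.** Detection and annotation series align strictly by default
  (equal lengths, identical frame indices). `truncate` pairs up to the
  shorter series with a warning; `fill` treats annotated frames missing
  from the detections as probability 0 — no proposal is evidence of
  absence.

## Behavioural metric choices

* **Swimming threshold** (5 px/s default): the assay distinguishes active
  swimming from hovering; no published value exists, so the threshold is a
  configuration parameter recorded in the output manifest. Transitions
  never span an absence gap.
* **Area covered** is grid-cell occupancy rather than convex hull or kernel
  density: it is monotone in observation time, robust to outliers, and
  directly interpretable as a fraction of the arena.
* **Turning angle** is the mean absolute angle in [0°, 180°] between
  successive displacement vectors. A signed mean would vanish on any
  approximately symmetric path; the absolute mean is the conventional
  sinuosity summary. Closed forms anchor the tests: collinear paths give
  0°, an axis-aligned square 90°, a regular hexagon 60°.
* **Exploration metrics** use the stationary object centroid and an
  inclusive 100 px radius.

## What the generator does and does not emulate

It emulates the statistical skeleton the validation machinery touches:
state-switching shelter use, within-arena movement with heading
persistence, score distributions conditioned on true presence, and
heavy-tailed centroid noise including object-confusion relocations. It does
not emulate swimming biomechanics, lighting or turbidity effects on the
detector, multi-fish scenes, posture, or any correlation between movement
speed and detection quality. Passing recovery tests therefore demonstrates
that the pipeline measures what it claims on data with known structure —
not that any particular detector reaches any particular accuracy on real
recordings; that always requires the manual-annotation validation this
package implements.

A related caveat: with relocation noise present, detector-derived
exploration metrics are biased toward the object (a relocated box may land
within the near radius), and jitter inflates turning angles whenever the
per-step displacement is not much larger than the jitter scale. Both
effects are visible in the recovery comparison written by
`analysis/04_behaviour_metrics.R` (time outside the shelter recovers to
well under 1 %, while the mean turning angle is reproducibly inflated).
They are properties of thresholded detector output in general, and one
reason raw trajectories should be validated before metric differences
between individuals are interpreted.

## Problem sizes

The packaged scenario uses 14 videos × 3,700 analysed frames (51,800
frames) with 1,085 positioning frames — the scale of a full validation
campaign — and runs in seconds. Unit tests use shorter series (hundreds to
tens of thousands of frames) sized so that each closed-form check has
negligible Monte-Carlo error at three standard errors.

## Limitations

* The matching percentage treats frames as exchangeable within the
  present/absent split; temporal autocorrelation is mitigated only by the
  proportional sampling used for positioning, mirroring the validation
  design this pipeline reproduces.
* The published-table RMSE convention is not identifiable (see above);
  cross-study RMSE comparisons should state the definition used.
* Behavioural metrics are computed on raw per-second centroids; a running
  median (`smooth_trajectory()`, window 3, never bridging absence gaps) is
  available but off by default, because smoothing changes turning-angle
  distributions in speed-dependent ways.
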