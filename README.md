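# arenatrack

Validation and behavioural metrics for detector-based tracking of a single
fish in an experimental arena.

Automated behavioural assays increasingly replace human video scoring with a
per-frame object detector: each analysed frame (one per second) yields a
classification probability — how confident the detector is that its best
object proposal is the fish — and a bounding box locating it in the
1280 × 768 px image. Because the fish is invisible to the camera while inside
its shelter, *detection ≡ outside the shelter*, and the thresholded
probability series doubles as a presence/absence ethogram. `arenatrack` is
for behavioural ecologists and aquaculture researchers who run such
pipelines and need to (a) validate the detector against manual annotation
before trusting it, and (b) turn its output into standard open-field
(activity) and novel-object (exploration) metrics.

## What it computes

**Classification validation.** For thresholds τ ∈ {0.5, …, 0.9} the
probability series is discretised (frame present iff *p* ≥ τ) and compared
frame-by-frame with a human-scored 0/1 series. Per video: the matching
percentage overall and split into the manually-present and manually-absent
parts (the overall value decomposes exactly as their frame-weighted mean).
Across videos (each weighted equally): mean, sample SD, the normal
approximation 95 % CI

&nbsp;&nbsp;&nbsp;&nbsp;mean ± 1.96 · SD / √n,

and an RMSE (frame-pooled by default, per-video available).

**Positioning validation.** The per-frame error is the Euclidean distance
between the centroids of the predicted and the manually drawn box (PASCAL
VOC XML, LabelImg dialect). Validation frames are sampled across videos in
proportion to each video's fish-present time (largest-remainder
apportionment) to mitigate autocorrelation. A localisation succeeds when its
error is at most the mean side length pooled over all manual boxes. Reported:
mean, SD, CI, RMSE = √(mean e²) and the success percentage.

**Behavioural metrics.** From the thresholded trajectory: time outside the
shelter, time swimming (transitions at ≥ 5 px/s within contiguous present
runs), mean absolute turning angle between successive displacement vectors,
and arena area covered (32 px grid-cell occupancy); for novel-object tests,
the minimum approach distance to the object centroid and the time spent
within 100 px of it.

**Synthetic arena.** Ground truth for all of the above: shelter occupancy as
a two-state Markov chain, movement as a correlated random walk re-emerging
at the shelter, detector scores as Beta laws conditioned on true presence
(error rates then follow from the Beta CDF at the threshold), and centroid
noise as Gaussian jitter plus a small-probability box relocation that
reproduces the small-mean / large-SD error structure of real detectors.

## Worked example

The `analysis/` scripts run the full study on the packaged scenario
(14 synthetic one-hour videos, 3,700 analysed frames each):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_validate_classification.R
Rscript analysis/03_validate_positioning.R --seed 1
Rscript analysis/04_behaviour_metrics.R
```

Step 2 prints the threshold sweep (mean matching % across the 14 videos,
with SD, CI and frame-pooled RMSE):

```
 threshold mean_pct sd_pct ci_low ci_high  rmse
       0.5    98.11 0.2957  97.95   98.26 13.75
       0.6    96.39 0.6581  96.05   96.74 18.99
       0.7    90.59 1.2314  89.95   91.24 30.67
       0.8    79.15 2.6715  77.76   80.55 45.66
       0.9    62.85 4.8524  60.31   65.40 60.95
```

Accuracy degrades as τ rises because the visible-fish score law
(Beta(8, 2)) loses mass below the threshold — the same pattern that makes
low thresholds preferable on real recordings. Step 3 summarises positioning
on 1,085 proportionally sampled present frames:

```
<positioning_result> n = 1085
  error: 13.53 +/- 78.82 px [8.84-18.22], RMSE 79.93 px
  success: 99.0% at threshold 65.00 px
```

The mean error is small but the SD is several times larger: rare relocated
boxes dominate the second moment while 99 % of frames sit within the 65 px
success threshold (the mean manual box side). Step 4 writes tidy per-video
behavioural metrics and checks them against the simulator's ground-truth
paths.

In R, the same pieces compose directly:

```r
library(arenatrack)
study <- simulate_study(default_scenario(n_videos = 14, seed = 1))
sweep <- sweep_thresholds(study, validation_config())
pos   <- run_positioning_validation(study, n_sample = 1085, seed = 1)
traj  <- build_trajectory(study$V01$detections, tau = 0.5)
activity_metrics(traj)
```

## Documentation

`vignettes/arena-tracking-validation.Rmd` describes the models, parameter
choices, numerical conventions and known limitations.
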