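Package: arenatrack
Title: Validation and Behavioural Metrics for Detector-Based Tracking of
    Single Fish in Experimental Arenas
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns per-frame object-detector output (a classification
    probability and a bounding box per frame, at one frame per second) from
    single-fish behavioural arenas into presence/absence series and
    trajectories, validates them against manual annotation (threshold
    sweeps, matching percentages split by manually-present and
    manually-absent parts, normal-approximation confidence intervals,
    RMSE; centroid positioning error against a success threshold derived
    from manually drawn box side lengths), and computes open-field
    activity and novel-object exploration metrics. A synthetic-arena
    simulator with known ground truth (two-state shelter occupancy,
    correlated random walk movement, Beta-distributed detector scores,
    heavy-tailed centroid noise) makes every stage verifiable by
    parameter recovery without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
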