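#!/usr/bin/env Rscript
# Step 2 — detection/classification validation.
#
# Reads the synthetic study written by 01_simulate.R from disk (detection +
# annotation CSVs, exactly the inputs a real deployment would provide),
# thresholds the detector probability at 0.5-0.9, and compares against the
# manual annotation frame by frame: per-video matching percentages split by
# manually-present / manually-absent parts, and cross-video mean, SD, 95%
# CI and RMSE per threshold and test type. Writes the summary tables under
# results/classification/ and a presence-validation figure for one video.
#
# Usage: Rscript analysis/02_validate_classification.R

suppressPackageStartupMessages({
  library(arenatrack)
  library(ggplot2)
})

study_dir <- file.path("results", "synthetic_study")
if (!dir.exists(study_dir)) stop("run analysis/01_simulate.R first")
manifest <- jsonlite::read_json(file.path(study_dir, "manifest.json"))

videos <- lapply(manifest$videos, function(m) {
  list(video_id = m$video_id, test_type = m$test_type,
       detections = read_detections(
         file.path(study_dir, paste0(m$video_id, "_detections.csv"))),
       annotations = read_annotations(
         file.path(study_dir, paste0(m$video_id, "_annotations.csv"))))
})

sw <- run_classification_validation(videos, validation_config(),
                                    out_dir = file.path("results",
                                                        "classification"))
tot <- sw$summary[sw$summary$test_type == "Total", ]
cat("Cross-video accuracy by threshold (Total):\n")
print(format(tot[, c("threshold", "mean_pct", "sd_pct", "ci_low", "ci_high",
                     "rmse")], digits = 4), row.names = FALSE)
best <- tot[which.max(tot$mean_pct), ]
cat(sprintf(
  "\nBest threshold %.1f: %.2f%% +/- %.2f%% [%.2f-%.2f], RMSE %.2f\n",
  best$threshold, best$mean_pct, best$sd_pct, best$ci_low, best$ci_high,
  best$rmse))
cat(sprintf("Present-part vs absent-part matching at 0.5: %.2f%% / %.2f%%\n",
            tot$mean_present_pct[tot$threshold == 0.5],
            tot$mean_absent_pct[tot$threshold == 0.5]))

fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
v1 <- videos[[1]]
p <- plot_presence_validation(v1$detections, v1$annotations, 0.5)
ggsave(file.path(fig_dir, "presence_validation_V01.pdf"), p,
       width = 10, height = 3)
cat(sprintf("Figure: %s\n",
            file.path(fig_dir, "presence_validation_V01.pdf")))
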