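#!/usr/bin/env Rscript
# Step 3 — positioning validation.
#
# Reads the study from disk, samples 1,085 fish-present frames across
# videos in proportion to each video's presence, reconstructs the manual
# bounding boxes from the ground-truth path (the synthetic stand-in for
# boxes a human would draw), and measures the centroid positioning error
# of the detector against them. Success = error at or below the mean side
# length of all manual boxes. Writes the per-frame error table and summary
# under results/positioning/ plus an error-vector figure.
#
# Usage: Rscript analysis/03_validate_positioning.R [--seed N]

suppressPackageStartupMessages({
  library(arenatrack)
  library(ggplot2)
})

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[which(args == "--seed") + 1L])
} else 1L

study_dir <- file.path("results", "synthetic_study")
if (!dir.exists(study_dir)) stop("run analysis/01_simulate.R first")
manifest <- jsonlite::read_json(file.path(study_dir, "manifest.json"))

read_video <- function(m) {
  truth <- utils::read.csv(
    file.path(study_dir, paste0(m$video_id, "_truth.csv")))
  det <- read_detections(
    file.path(study_dir, paste0(m$video_id, "_detections.csv")))
  ann <- read_annotations(
    file.path(study_dir, paste0(m$video_id, "_annotations.csv")))
  vis <- truth$visible == 1
  manual <- data.frame(
    video_id = m$video_id, frame_index = truth$frame_index[vis],
    x_min = pmax(truth$x[vis] - m$box_halfwidth, 0),
    y_min = pmax(truth$y[vis] - m$box_halfheight, 0),
    x_max = pmin(truth$x[vis] + m$box_halfwidth, m$arena_width),
    y_max = pmin(truth$y[vis] + m$box_halfheight, m$arena_height))
  predicted <- cbind(data.frame(video_id = m$video_id), det)
  list(annotations = ann, manual = manual, predicted = predicted)
}

videos <- lapply(manifest$videos, read_video)
picked <- sample_validation_frames(lapply(videos, `[[`, "annotations"),
                                   n_total = 1085, seed = seed)
manual <- do.call(rbind, lapply(videos, `[[`, "manual"))
key <- function(df) paste(df$video_id, df$frame_index)
manual <- manual[key(manual) %in% key(picked), ]
predicted <- do.call(rbind, lapply(videos, `[[`, "predicted"))

res <- validate_positioning(predicted, manual)
out <- file.path("results", "positioning")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(res$frames, file.path(out, "positioning_frames.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(n = res$n, mean_px = res$mean_px, sd_px = res$sd_px,
             ci_low = res$ci_low, ci_high = res$ci_high,
             rmse_px = res$rmse_px,
             success_threshold_px = res$success_threshold_px,
             success_pct = res$success_pct),
  file.path(out, "positioning_summary.csv"), row.names = FALSE)

print(res)
cat(sprintf("Errors <= 25 px: %.1f%% of sampled frames\n",
            100 * mean(res$errors <= 25)))

fig_dir <- file.path("results", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
ggsave(file.path(fig_dir, "positioning_errors.pdf"),
       plot_positioning_errors(res), width = 8, height = 5)
cat(sprintf("Figure: %s\n", file.path(fig_dir, "positioning_errors.pdf")))
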