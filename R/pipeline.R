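# Pipeline orchestration: scenario configuration, multi-video synthetic
# studies, and the run_* steps the analysis scripts drive. Every run writes
# a JSON manifest (config snapshot + seed) sufficient to reproduce its
# outputs bit for bit.

#' Default synthetic study scenario
#'
#' The study conditions the simulator emulates: 14 one-hour videos at one
#' analysed frame per second, half open-field activity tests and half
#' novel-object exploration tests, sharing one arena with a shelter in the
#' top-left corner and (for exploration videos) a novel object right of
#' centre. Per-video seeds are derived deterministically from `seed`.
#'
#' @param n_videos Number of videos (default 14).
#' @param duration Seconds per video (default 3600).
#' @param seed Base integer seed.
#' @param sim Template [simulation_params()]; per-video duration and seed
#'   are filled in.
#' @param noise A [noise_params()] shared by all videos.
#' @param arena An [arena_geometry()]; the default has a 160 px shelter
#'   square at the origin and an object centroid at (900, 400).
#' @return A list of per-video specs of class `scenario`.
#' @export
default_scenario <- function(n_videos = 14, duration = 3600, seed = 1L,
                             sim = NULL, noise = noise_params(),
                             arena = arena_geometry(
                               shelter_region = c(0, 0, 160, 160),
                               object_centroid = c(900, 400))) {
  if (n_videos < 1) stop("need at least one video", call. = FALSE)
  videos <- lapply(seq_len(n_videos), function(i) {
    p <- sim %||% simulation_params(arena = arena)
    p$duration <- duration
    p$arena <- arena
    p$seed <- derive_seed(seed, sprintf("video-%02d", i))
    list(video_id = sprintf("V%02d", i),
         test_type = if (i <= ceiling(n_videos / 2)) "ACT" else "EXP",
         params = p, noise = noise)
  })
  structure(videos, class = c("scenario", "list"), seed = seed)
}

#' Simulate a whole study
#'
#' Runs [simulate_video()] for every video of a scenario.
#'
#' @param scenario A scenario from [default_scenario()] or
#'   [read_scenario()].
#' @return A list of `synthetic_video` objects, named by video id.
#' @export
simulate_study <- function(scenario) {
  out <- lapply(scenario, function(v) {
    simulate_video(v$params, v$noise, video_id = v$video_id,
                   test_type = v$test_type)
  })
  stats::setNames(out, vapply(scenario, `[[`, character(1), "video_id"))
}

#' Read a scenario from a YAML file
#'
#' The file mirrors the [simulation_params()] / [noise_params()] field
#' names; see `inst/extdata/scenario_default.yaml` for the layout.
#'
#' @param path YAML file.
#' @param seed Optional integer overriding the file's `seed` entry.
#' @return A scenario (see [default_scenario()]).
#' @export
read_scenario <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(seed)) cfg$seed <- seed
  arena <- do.call(arena_geometry, cfg$arena %||% list())
  noise <- do.call(noise_params, cfg$noise %||% list())
  sim_fields <- cfg$simulation %||% list()
  sim_fields$arena <- arena
  sim <- do.call(simulation_params, sim_fields)
  default_scenario(n_videos = cfg$n_videos %||% 14,
                   duration = sim$duration,
                   seed = cfg$seed %||% 1L,
                   sim = sim, noise = noise, arena = arena)
}

#' Write a synthetic study to disk
#'
#' Per video: a detection CSV, an annotation CSV and a ground-truth CSV
#' (`frame_index, visible, x, y`); plus a `manifest.json` recording the
#' scenario parameters and seeds.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in study) {
    write_detections(v$detections,
                     file.path(dir, paste0(v$video_id, "_detections.csv")))
    write_annotations(v$occupancy,
                      file.path(dir, paste0(v$video_id, "_annotations.csv")))
    truth <- data.frame(frame_index = v$truth$frame_index,
                        visible = as.integer(v$truth$present),
                        x = fmt_num(v$truth$x), y = fmt_num(v$truth$y))
    utils::write.table(truth,
                       file.path(dir, paste0(v$video_id, "_truth.csv")),
                       sep = ",", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  manifest <- list(
    package = "arenatrack",
    version = as.character(utils::packageVersion("arenatrack")),
    n_videos = length(study),
    videos = lapply(study, function(v) {
      list(video_id = v$video_id, test_type = v$test_type,
           duration = v$params$duration, seed = v$params$seed,
           noise_seed = v$noise$seed,
           p_exit = v$params$p_exit, p_enter = v$params$p_enter,
           step_sigma = v$params$step_sigma,
           persistence = v$params$persistence,
           jitter_sigma = v$noise$jitter_sigma,
           outlier_prob = v$noise$outlier_prob,
           box_halfwidth = v$noise$box_halfwidth,
           box_halfheight = v$noise$box_halfheight,
           arena_width = v$params$arena$width,
           arena_height = v$params$arena$height)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the classification validation step
#'
#' Threshold sweep over a study; writes the Table-1-style summary CSV and
#' the per-video long-format CSV, plus a manifest.
#'
#' @param study A list of videos (see [sweep_thresholds()]).
#' @param config A [validation_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return The `sweep_summary`, invisibly when writing.
#' @export
run_classification_validation <- function(study,
                                          config = validation_config(),
                                          out_dir = NULL) {
  sw <- sweep_thresholds(study, config)
  if (is.null(out_dir)) return(sw)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sw$summary,
                   file.path(out_dir, "classification_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(sw$per_video,
                   file.path(out_dir, "classification_per_video.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(step = "classification_validation",
         thresholds = config$thresholds, confidence_z = config$confidence_z,
         rmse_mode = config$rmse_mode,
         n_videos = length(unique(sw$per_video$video_id)),
         n_frames = sum(sw$per_video$n_frames[
           sw$per_video$threshold == config$thresholds[1]])),
    file.path(out_dir, "classification_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sw)
}

#' Run the positioning validation step
#'
#' Samples fish-present frames in proportion to each video's presence
#' ([sample_validation_frames()]), pairs the detector's boxes with the
#' manual stand-in boxes centred on the true path ([truth_boxes()]), and
#' summarises the centroid errors.
#'
#' @param study A list of `synthetic_video` objects.
#' @param n_sample Frames to sample across the study; `NULL` uses every
#'   present frame.
#' @param seed Sampling seed.
#' @param z Normal quantile for the CI.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `positioning_result` (see [validate_positioning()]).
#' @export
run_positioning_validation <- function(study, n_sample = 1085, seed = 1L,
                                       z = 1.96, out_dir = NULL) {
  stopifnot(all(vapply(study, inherits, logical(1), "synthetic_video")))
  manual <- do.call(rbind, lapply(study, truth_boxes))
  if (!is.null(n_sample)) {
    picked <- sample_validation_frames(study, n_sample, seed = seed)
    key <- function(df) paste(df$video_id, df$frame_index, sep = "\r")
    manual <- manual[key(manual) %in% key(picked), , drop = FALSE]
  }
  predicted <- do.call(rbind, lapply(study, function(v) {
    cbind(data.frame(video_id = v$video_id), v$detections)
  }))
  res <- validate_positioning(predicted, manual, z = z)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$frames,
                     file.path(out_dir, "positioning_frames.csv"),
                     row.names = FALSE)
    summary_df <- data.frame(
      n = res$n, mean_px = res$mean_px, sd_px = res$sd_px,
      ci_low = res$ci_low, ci_high = res$ci_high, rmse_px = res$rmse_px,
      success_threshold_px = res$success_threshold_px,
      success_pct = res$success_pct)
    utils::write.csv(summary_df,
                     file.path(out_dir, "positioning_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(step = "positioning_validation", n_sample = n_sample,
           seed = seed, z = z),
      file.path(out_dir, "positioning_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Run the behavioural-metrics step
#'
#' Builds a trajectory per video from thresholded detections and computes
#' the metric bundle for its test type: activity metrics for open-field
#' videos, exploration metrics (plus time outside) for novel-object videos.
#' Results are returned — and optionally written — in tidy long format.
#'
#' @param study A list of videos: `synthetic_video` objects or lists with
#'   `detections` and `test_type`.
#' @param tau Presence threshold.
#' @param act_cfg An [activity_config()].
#' @param exp_cfg An [exploration_config()], or `NULL` to take the object
#'   centroid from the arena geometry; exploration videos with no object
#'   available are skipped with a message.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A tidy data frame: `video_id`, `test_type`, `metric`, `value`,
#'   `units`.
#' @export
run_behaviour_metrics <- function(study, tau = 0.5,
                                  act_cfg = activity_config(),
                                  exp_cfg = NULL, out_dir = NULL) {
  rows <- lapply(study, function(v) {
    det <- if (inherits(v, "synthetic_video")) v$detections else v$detections
    type <- if (inherits(v, "synthetic_video")) v$test_type
            else v$test_type %||% "ACT"
    id <- if (inherits(v, "synthetic_video")) v$video_id
          else v$video_id %||% video_id(det)
    traj <- build_trajectory(det, tau)
    if (type == "ACT") {
      m <- activity_metrics(traj, act_cfg)
      tidy_metrics(id, type, m,
                   units = c("s", "s", "deg", "cells", "fraction"))
    } else {
      cfg <- exp_cfg
      if (is.null(cfg)) {
        oc <- if (inherits(v, "synthetic_video"))
          v$params$arena$object_centroid else NULL
        if (is.null(oc)) {
          message(sprintf(
            "video %s: no object centroid configured; exploration metrics skipped",
            id))
          return(NULL)
        }
        cfg <- exploration_config(oc)
      }
      m <- exploration_metrics(traj, cfg)
      tidy_metrics(id, type, m, units = c("s", "px", "s"))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "behaviour_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(step = "behaviour_metrics", tau = tau,
           speed_threshold = act_cfg$speed_threshold,
           grid_cell = act_cfg$grid_cell,
           near_radius = if (!is.null(exp_cfg)) exp_cfg$near_radius else 100),
      file.path(out_dir, "metrics_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

tidy_metrics <- function(id, type, m, units) {
  data.frame(video_id = id, test_type = type,
             metric = names(m), value = as.numeric(m[1, ]),
             units = units)
}
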