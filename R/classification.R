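# Detection/classification validation: thresholding of the detector's
# per-frame probability, frame-by-frame comparison with manual annotation,
# and aggregation across videos into a threshold-sweep summary table.

#' Validation configuration
#'
#' @param thresholds Probability thresholds to sweep, strictly increasing,
#'   each in (0, 1). Default `c(0.5, 0.6, 0.7, 0.8, 0.9)`.
#' @param confidence_z Normal quantile for the confidence interval of the
#'   cross-video mean (default 1.96, a 95% interval).
#' @param rmse_mode `"frame_pooled"` (RMSE of the pooled per-frame 0/1
#'   mismatch, on the percentage scale) or `"per_video"` (root mean square
#'   of per-video error percentages).
#' @param align_mode Passed to [align_series()].
#' @return An object of class `validation_config`.
#' @export
validation_config <- function(thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              confidence_z = 1.96,
                              rmse_mode = c("frame_pooled", "per_video"),
                              align_mode = "strict") {
  rmse_mode <- match.arg(rmse_mode)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L || any(thresholds <= 0) ||
      any(thresholds >= 1)) {
    stop("`thresholds` must lie in (0, 1)", call. = FALSE)
  }
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  }
  assert_scalar_number(confidence_z, "confidence_z",
                       lower = .Machine$double.eps)
  structure(list(thresholds = thresholds, confidence_z = confidence_z,
                 rmse_mode = rmse_mode, align_mode = align_mode),
            class = "validation_config")
}

#' Threshold a probability series into presence/absence
#'
#' A frame counts as "fish present" when its probability is at or above the
#' threshold (the boundary counts as present).
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param tau Threshold in (0, 1).
#' @return Integer vector of 0/1 predictions.
#' @examples
#' threshold_series(c(0, 1, 0.6), 0.5) # 0 1 1
#' @export
threshold_series <- function(probabilities, tau) {
  assert_scalar_number(tau, "tau",
                       lower = .Machine$double.eps,
                       upper = 1 - .Machine$double.eps)
  if (anyNA(probabilities) || any(probabilities < 0) ||
      any(probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  as.integer(probabilities >= tau)
}

#' Frame-by-frame matching of predicted and manual presence
#'
#' Computes the matching percentage over all frames, and separately over
#' the manually-present and manually-absent parts of the video. A part with
#' no frames yields an explicitly missing (`NA`) percentage, never 0 or
#' 100. The overall percentage always decomposes exactly as the
#' frame-weighted mean of the two parts.
#'
#' @param predicted,manual Equal-length 0/1 vectors.
#' @return A one-row data frame: `n_frames`, `n_present`, `n_absent`,
#'   `n_match`, `n_match_present`, `n_match_absent`, `overall_pct`,
#'   `present_pct`, `absent_pct`.
#' @export
match_result <- function(predicted, manual) {
  if (length(predicted) != length(manual)) {
    stop(sprintf("alignment error: %d predicted vs %d manual frames",
                 length(predicted), length(manual)), call. = FALSE)
  }
  n <- length(manual)
  if (n == 0L) stop("empty input: no frames to compare", call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(manual %in% c(0, 1))) {
    stop("predicted and manual values must be 0 or 1", call. = FALSE)
  }
  match <- predicted == manual
  pres <- manual == 1
  n_present <- sum(pres)
  n_absent <- n - n_present
  n_match_present <- sum(match & pres)
  n_match_absent <- sum(match & !pres)
  data.frame(
    n_frames = n, n_present = n_present, n_absent = n_absent,
    n_match = n_match_present + n_match_absent,
    n_match_present = n_match_present, n_match_absent = n_match_absent,
    overall_pct = 100 * (n_match_present + n_match_absent) / n,
    present_pct = if (n_present > 0) 100 * n_match_present / n_present
                  else NA_real_,
    absent_pct = if (n_absent > 0) 100 * n_match_absent / n_absent
                 else NA_real_)
}

#' Normal-approximation confidence interval for a mean
#'
#' The interval convention used throughout the summary tables:
#' `mean +/- z * sd / sqrt(n)`.
#'
#' @param mean,sd Sample mean and sample standard deviation.
#' @param n Number of observations (>= 2).
#' @param z Normal quantile (default 1.96).
#' @return Named numeric `c(low, high)`.
#' @examples
#' ci_of_mean(92.79, 6.78, 14) # c(89.24, 96.34) at 2 dp
#' @export
ci_of_mean <- function(mean, sd, n, z = 1.96) {
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd", lower = 0)
  assert_scalar_number(z, "z", lower = .Machine$double.eps)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2) {
    stop("`n` must be at least 2 for a confidence interval", call. = FALSE)
  }
  half <- z * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

#' Threshold sweep over a set of validated videos
#'
#' For each threshold, compares each video's thresholded detections with
#' its manual annotation ([match_result()]), then aggregates across videos:
#' mean and sample SD of the per-video overall matching percentage (each
#' video weighted equally regardless of length), its confidence interval
#' ([ci_of_mean()]), and an RMSE. Aggregates are reported per test type
#' (activity "ACT", exploration "EXP") and pooled over all videos
#' ("Total").
#'
#' @param videos A list; each element a list with elements `detections`
#'   (a [detection_series()]), `annotations` (an [annotation_series()])
#'   and `test_type` (`"ACT"` or `"EXP"`). A `synthetic_video` from
#'   [simulate_video()] works as-is (its `occupancy` is the annotation).
#' @param config A [validation_config()].
#' @return An object of class `sweep_summary`: a list with `per_video`
#'   (long-format per-video results) and `summary` (one row per test type
#'   x threshold), plus the config used.
#' @export
sweep_thresholds <- function(videos, config = validation_config()) {
  stopifnot(inherits(config, "validation_config"))
  if (length(videos) == 0L) stop("need at least one video", call. = FALSE)
  videos <- lapply(videos, as_validation_video)
  per_video <- do.call(rbind, lapply(videos, function(v) {
    aligned <- align_series(v$detections, v$annotations,
                            mode = config$align_mode)
    do.call(rbind, lapply(config$thresholds, function(tau) {
      pred <- threshold_series(aligned$probability, tau)
      res <- match_result(pred, aligned$present)
      cbind(data.frame(video_id = v$video_id, test_type = v$test_type,
                       threshold = tau), res)
    }))
  }))
  rownames(per_video) <- NULL
  summary <- summarize_sweep(per_video, config)
  structure(list(per_video = per_video, summary = summary, config = config),
            class = "sweep_summary")
}

as_validation_video <- function(v) {
  if (inherits(v, "synthetic_video")) {
    return(list(video_id = v$video_id, test_type = v$test_type,
                detections = v$detections, annotations = v$occupancy))
  }
  if (is.null(v$detections) || is.null(v$annotations)) {
    stop("each video needs `detections` and `annotations`", call. = FALSE)
  }
  list(video_id = v$video_id %||% video_id(v$detections) %||% "video",
       test_type = v$test_type %||% "ACT",
       detections = v$detections, annotations = v$annotations)
}

summarize_sweep <- function(per_video, config) {
  groups <- c(split(per_video, per_video$test_type),
              list(Total = per_video))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    do.call(rbind, lapply(unique(df$threshold), function(tau) {
      rows <- df[df$threshold == tau, ]
      n_videos <- nrow(rows)
      m <- mean(rows$overall_pct)
      s <- if (n_videos >= 2) stats::sd(rows$overall_pct) else NA_real_
      ci <- if (n_videos >= 2) ci_of_mean(m, s, n_videos, config$confidence_z)
            else c(low = NA_real_, high = NA_real_)
      data.frame(test_type = g, threshold = tau, n_videos = n_videos,
                 n_frames = sum(rows$n_frames),
                 mean_pct = m, sd_pct = s,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 rmse = rmse_from_rows(rows, config$rmse_mode),
                 mean_present_pct = mean(rows$present_pct, na.rm = TRUE),
                 mean_absent_pct = mean(rows$absent_pct, na.rm = TRUE))
    }))
  }))
  rownames(out) <- NULL
  out
}

rmse_from_rows <- function(rows, mode) {
  if (mode == "frame_pooled") {
    100 * sqrt(1 - sum(rows$n_match) / sum(rows$n_frames))
  } else {
    sqrt(mean((100 - rows$overall_pct)^2))
  }
}

#' Classification RMSE across videos at one threshold
#'
#' `"frame_pooled"`: 100 times the square root of the mismatch fraction
#' pooled over every frame of every video. `"per_video"`: the root mean
#' square of the per-video error percentages `100 - overall_pct`.
#'
#' @param videos As in [sweep_thresholds()].
#' @param tau Threshold in (0, 1).
#' @param mode RMSE definition (see above).
#' @param align_mode Passed to [align_series()].
#' @return A single number on the percentage scale.
#' @export
rmse_classification <- function(videos, tau,
                                mode = c("frame_pooled", "per_video"),
                                align_mode = "strict") {
  mode <- match.arg(mode)
  cfg <- validation_config(thresholds = tau, rmse_mode = mode,
                           align_mode = align_mode)
  sw <- sweep_thresholds(videos, cfg)
  s <- sw$summary
  s$rmse[s$test_type == "Total" & s$threshold == tau]
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf("<sweep_summary> %d video(s), thresholds %s\n",
              length(unique(x$per_video$video_id)),
              paste(x$config$thresholds, collapse = ", ")))
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) round(col, 2))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
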