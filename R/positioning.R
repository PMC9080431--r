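# Positioning validation: Euclidean error between predicted and manually
# drawn box centroids, summarised against a success threshold equal to the
# mean side length of all manual boxes.

#' Centroid positioning error
#'
#' Euclidean distance, in pixels, between the centroids of predicted and
#' manual boxes. Vectorised over rows.
#'
#' @param predicted,manual Data frames of boxes (equal row counts).
#' @return Numeric vector of distances.
#' @examples
#' centroid_error(bounding_box(0, 0, 10, 10), bounding_box(10, 0, 20, 10)) # 10
#' @export
centroid_error <- function(predicted, manual) {
  if (nrow(predicted) != nrow(manual)) {
    stop(sprintf("box count mismatch: %d predicted vs %d manual",
                 nrow(predicted), nrow(manual)), call. = FALSE)
  }
  cp <- bbox_centroid(predicted)
  cm <- bbox_centroid(manual)
  sqrt((cp$x - cm$x)^2 + (cp$y - cm$y)^2)
}

#' Positioning success threshold
#'
#' The error threshold below which a localisation counts as successful:
#' the mean over the pooled side lengths (each box contributes its width
#' and its height once) of all manually drawn boxes. `"per_box_mean"`
#' averages each box's two sides first, then averages across boxes; the two
#' conventions coincide unless box counts are weighted unevenly.
#'
#' @param manual_boxes Data frame of manual boxes (>= 1 row).
#' @param method `"pooled_sides"` (default) or `"per_box_mean"`.
#' @return Threshold in pixels.
#' @examples
#' success_threshold(bounding_box(0, 0, 100, 200)) # 150
#' @export
success_threshold <- function(manual_boxes,
                              method = c("pooled_sides", "per_box_mean")) {
  method <- match.arg(method)
  validate_boxes(manual_boxes)
  if (nrow(manual_boxes) == 0L) {
    stop("need at least one manual box", call. = FALSE)
  }
  if (method == "pooled_sides") {
    mean(box_side_lengths(manual_boxes))
  } else {
    mean((manual_boxes$x_max - manual_boxes$x_min +
          manual_boxes$y_max - manual_boxes$y_min) / 2)
  }
}

#' Summarise positioning errors
#'
#' Mean, sample SD, normal-approximation confidence interval
#' ([ci_of_mean()]), RMSE (root mean of squared errors) and the percentage
#' of errors at or below the success threshold. The identity
#' `rmse^2 = mean^2 + population variance` holds by construction and is a
#' useful cross-check on any reported triple.
#'
#' @param errors Non-negative distances in pixels (>= 2 values).
#' @param threshold Success threshold in pixels (> 0), typically from
#'   [success_threshold()].
#' @param z Normal quantile for the CI (default 1.96).
#' @return An object of class `positioning_result`: a list with `errors`,
#'   `n`, `mean_px`, `sd_px`, `ci_low`, `ci_high`, `rmse_px`,
#'   `success_threshold_px`, `success_pct`.
#' @export
summarize_positioning <- function(errors, threshold, z = 1.96) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("no errors to summarise", call. = FALSE)
  if (anyNA(errors) || any(errors < 0)) {
    stop("errors must be non-negative and non-missing", call. = FALSE)
  }
  assert_scalar_number(threshold, "threshold",
                       lower = .Machine$double.eps)
  n <- length(errors)
  m <- mean(errors)
  s <- if (n >= 2) stats::sd(errors) else NA_real_
  ci <- if (n >= 2) ci_of_mean(m, s, n, z) else c(low = NA_real_,
                                                  high = NA_real_)
  structure(
    list(errors = errors, n = n, mean_px = m, sd_px = s,
         ci_low = ci[["low"]], ci_high = ci[["high"]],
         rmse_px = sqrt(mean(errors^2)),
         success_threshold_px = threshold,
         success_pct = 100 * mean(errors <= threshold)),
    class = "positioning_result")
}

#' @export
print.positioning_result <- function(x, ...) {
  cat(sprintf(
    "<positioning_result> n = %d\n  error: %.2f +/- %.2f px [%.2f-%.2f], RMSE %.2f px\n  success: %.1f%% at threshold %.2f px\n",
    x$n, x$mean_px, x$sd_px, x$ci_low, x$ci_high, x$rmse_px,
    x$success_pct, x$success_threshold_px))
  invisible(x)
}

#' Sample frames for manual positioning validation
#'
#' Draws `n_total` fish-present frames across videos for manual box
#' annotation. To mitigate temporal autocorrelation, each video's quota is
#' proportional to its number of present frames (largest-remainder
#' apportionment; remainder ties broken by video order); frames are then
#' drawn uniformly without replacement within each video.
#'
#' @param videos A list of [annotation_series()] (or of `synthetic_video`s,
#'   whose occupancy is used).
#' @param n_total Total number of frames to sample.
#' @param seed Integer seed.
#' @return A data frame with columns `video_id`, `frame_index`, sorted by
#'   video then frame.
#' @export
sample_validation_frames <- function(videos, n_total, seed = 1L) {
  assert_scalar_number(n_total, "n_total", lower = 1)
  ann <- lapply(videos, function(v) {
    if (inherits(v, "synthetic_video")) v$occupancy else v
  })
  lapply(ann, validate_annotation_series)
  ids <- vapply(seq_along(ann), function(i) {
    video_id(ann[[i]]) %||% sprintf("video%02d", i)
  }, character(1))
  counts <- vapply(ann, function(a) sum(a$present == 1L), numeric(1))
  total <- sum(counts)
  if (total < n_total) {
    stop(sprintf(
      "insufficient present frames: %d available, %d requested",
      total, n_total), call. = FALSE)
  }
  quotas <- largest_remainder(n_total * counts / total)
  # quota can exceed a video's present count only through rounding-up; push
  # any excess onto videos with room, in order
  over <- quotas > counts
  if (any(over)) {
    excess <- sum(quotas[over] - counts[over])
    quotas[over] <- counts[over]
    room <- counts - quotas
    for (i in order(-room)) {
      take <- min(excess, room[i])
      quotas[i] <- quotas[i] + take
      excess <- excess - take
      if (excess == 0) break
    }
  }
  out <- local_seed(derive_seed(seed, "frame-sampling"), {
    do.call(rbind, lapply(seq_along(ann), function(i) {
      if (quotas[i] == 0L) return(NULL)
      pres <- ann[[i]]$frame_index[ann[[i]]$present == 1L]
      picked <- sort(sample(pres, quotas[i], replace = FALSE))
      data.frame(video_id = ids[i], frame_index = picked)
    }))
  })
  rownames(out) <- NULL
  out
}

#' Largest-remainder apportionment of fractional quotas
#'
#' Rounds a vector of non-negative fractional quotas to integers that keep
#' the original sum: floors first, then distributes the leftover units by
#' descending fractional remainder, ties broken by position.
#'
#' @param x Non-negative quotas whose sum is (numerically) an integer.
#' @return Integer vector with `sum(x)` preserved.
#' @export
largest_remainder <- function(x) {
  if (any(x < 0)) stop("quotas must be non-negative", call. = FALSE)
  target <- round(sum(x))
  base <- floor(x + 1e-9)          # guard against 33.999999... artefacts
  left <- as.integer(target - sum(base))
  frac <- x - base
  quota <- as.integer(base)
  if (left > 0L) {
    take <- order(-frac, seq_along(x))[seq_len(left)]
    quota[take] <- quota[take] + 1L
  }
  quota
}

#' Validate positioning on a set of videos
#'
#' Joins predicted boxes (from detections) with manual boxes on
#' `(video_id, frame_index)`, computes centroid errors, derives the success
#' threshold from the manual boxes, and summarises.
#'
#' @param predicted Data frame of predicted boxes with `video_id` and
#'   `frame_index` columns (e.g. detection rows).
#' @param manual Data frame of manual boxes with `video_id` and
#'   `frame_index` columns (e.g. from [parse_voc_boxes()] +
#'   [parse_frame_key()], or [truth_boxes()]).
#' @param z Normal quantile for the CI.
#' @return A `positioning_result` (see [summarize_positioning()]) with an
#'   extra element `frames`, the per-frame error table.
#' @export
validate_positioning <- function(predicted, manual, z = 1.96) {
  for (df in list(predicted, manual)) {
    if (!all(c("video_id", "frame_index") %in% names(df))) {
      stop("boxes need video_id and frame_index columns", call. = FALSE)
    }
  }
  validate_boxes(predicted)
  validate_boxes(manual)
  key <- function(df) paste(df$video_id, df$frame_index, sep = "\r")
  idx <- match(key(manual), key(predicted))
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0) {
    message(sprintf("%d of %d manual frame(s) have no predicted box; dropped",
                    n_unmatched, nrow(manual)))
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no frames in common between predicted and manual",
                       call. = FALSE)
  man <- manual[keep, , drop = FALSE]
  pred <- predicted[idx[keep], , drop = FALSE]
  errors <- centroid_error(pred, man)
  res <- summarize_positioning(errors, success_threshold(man), z = z)
  cp <- bbox_centroid(pred)
  cm <- bbox_centroid(man)
  res$frames <- data.frame(video_id = man$video_id,
                           frame_index = man$frame_index,
                           pred_x = cp$x, pred_y = cp$y,
                           manual_x = cm$x, manual_y = cm$y,
                           error_px = errors)
  res
}
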