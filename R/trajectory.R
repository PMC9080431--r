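# Trajectories and the behavioural metrics computed from them.
#
# A trajectory is the per-frame position of the fish over one video:
# present frames carry a centroid, absent frames carry NA. Contiguous runs
# of present frames ("segments") matter because displacement-based metrics
# must never bridge an absence gap.

#' Trajectory
#'
#' @param frame_index Integer frame numbers, strictly increasing.
#' @param present Logical (or 0/1) presence per frame.
#' @param x,y Centroid coordinates in pixels; must be non-missing exactly
#'   on present frames.
#' @param video_id Video label.
#' @param frame_interval Seconds between frames.
#' @return A data frame with columns `frame_index`, `present`, `x`, `y`,
#'   class `trajectory`.
#' @export
trajectory <- function(frame_index, present, x, y, video_id = "video",
                       frame_interval = 1) {
  out <- data.frame(frame_index = as.integer(frame_index),
                    present = as.logical(present),
                    x = as.numeric(x), y = as.numeric(y))
  attr(out, "video_id") <- video_id
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("trajectory", "data.frame")
  validate_trajectory(out)
}

validate_trajectory <- function(traj) {
  fi <- traj$frame_index
  if (length(fi) > 1L && any(diff(fi) <= 0)) {
    stop("frame_index must be strictly increasing", call. = FALSE)
  }
  has_pos <- !is.na(traj$x) & !is.na(traj$y)
  if (any(traj$present != has_pos)) {
    stop("centroid must be present exactly on present frames",
         call. = FALSE)
  }
  invisible(traj)
}

#' Contiguous present segments of a trajectory
#'
#' Maximal runs of consecutive present frames (consecutive both in row
#' order and in frame index). Displacements and turning angles are only
#' evaluated within a segment.
#'
#' @param traj A [trajectory()].
#' @return A data frame with columns `start_row`, `end_row`, `n_frames`.
#' @export
trajectory_segments <- function(traj) {
  validate_trajectory(traj)
  n <- nrow(traj)
  empty <- data.frame(start_row = integer(), end_row = integer(),
                      n_frames = integer())
  if (n == 0L) return(empty)
  # a new segment starts where presence switches on, or a frame gap occurs
  contiguous <- c(FALSE, diff(traj$frame_index) == 1L)
  new_seg <- traj$present & !(c(FALSE, traj$present[-n]) & contiguous)
  seg_id <- cumsum(new_seg)
  seg_id[!traj$present] <- NA
  if (all(is.na(seg_id))) return(empty)
  rows <- split(seq_len(n)[!is.na(seg_id)], seg_id[!is.na(seg_id)])
  out <- data.frame(
    start_row = vapply(rows, min, integer(1)),
    end_row = vapply(rows, max, integer(1)))
  out$n_frames <- out$end_row - out$start_row + 1L
  rownames(out) <- NULL
  out
}

#' Build a trajectory from thresholded detections
#'
#' A frame is present when its detection probability is at or above `tau`;
#' its position is the bounding-box centroid. Absent frames carry no
#' position.
#'
#' @param detections A [detection_series()].
#' @param tau Presence threshold in (0, 1).
#' @return A [trajectory()].
#' @export
build_trajectory <- function(detections, tau = 0.5) {
  validate_detection_series(detections)
  pred <- threshold_series(detections$probability, tau) == 1L
  cen <- bbox_centroid(detections)
  trajectory(detections$frame_index, pred,
             ifelse(pred, cen$x, NA_real_), ifelse(pred, cen$y, NA_real_),
             video_id = video_id(detections),
             frame_interval = frame_interval(detections))
}

#' Median-smooth a trajectory's centroids
#'
#' Running median (default window 3) applied per axis within each present
#' segment; segment endpoints and absent frames are untouched, and
#' smoothing never bridges an absence gap. Off by default throughout the
#' pipeline: metrics are computed on raw per-second centroids unless a
#' smoothed trajectory is passed explicitly.
#'
#' @param traj A [trajectory()].
#' @param window Odd window width (default 3).
#' @return A [trajectory()] with smoothed centroids.
#' @export
smooth_trajectory <- function(traj, window = 3) {
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd number >= 3", call. = FALSE)
  }
  validate_trajectory(traj)
  segs <- trajectory_segments(traj)
  x <- traj$x
  y <- traj$y
  for (i in seq_len(nrow(segs))) {
    rows <- segs$start_row[i]:segs$end_row[i]
    if (length(rows) >= window) {
      x[rows] <- stats::runmed(traj$x[rows], window, endrule = "keep")
      y[rows] <- stats::runmed(traj$y[rows], window, endrule = "keep")
    }
  }
  trajectory(traj$frame_index, traj$present, x, y,
             video_id = video_id(traj),
             frame_interval = frame_interval(traj))
}

#' Activity-test configuration
#'
#' @param speed_threshold Speed (pixels/second) at or above which a frame
#'   transition counts as swimming. Default 5.
#' @param grid_cell Side (pixels) of the square cells used for area
#'   coverage. Default 32, giving a 40 x 24 grid on a 1280 x 768 arena.
#' @param arena An [arena_geometry()].
#' @return An object of class `activity_config`.
#' @export
activity_config <- function(speed_threshold = 5, grid_cell = 32,
                            arena = arena_geometry()) {
  assert_scalar_number(speed_threshold, "speed_threshold", lower = 0)
  assert_scalar_number(grid_cell, "grid_cell",
                       lower = .Machine$double.eps)
  if (grid_cell > arena$width || grid_cell > arena$height) {
    stop("`grid_cell` must fit at least one cell per axis", call. = FALSE)
  }
  structure(list(speed_threshold = speed_threshold, grid_cell = grid_cell,
                 arena = arena),
            class = "activity_config")
}

#' Exploration-test configuration
#'
#' @param object_centroid Point `c(x, y)`: centroid of the novel object.
#' @param near_radius Radius (pixels) defining "near the object".
#'   Default 100.
#' @return An object of class `exploration_config`.
#' @export
exploration_config <- function(object_centroid, near_radius = 100) {
  object_centroid <- as.numeric(object_centroid)
  if (length(object_centroid) != 2L || anyNA(object_centroid)) {
    stop("`object_centroid` must be a point c(x, y)", call. = FALSE)
  }
  assert_scalar_number(near_radius, "near_radius",
                       lower = .Machine$double.eps)
  structure(list(object_centroid = object_centroid,
                 near_radius = near_radius),
            class = "exploration_config")
}

#' Time spent outside the shelter
#'
#' Number of present frames times the frame interval. Visibility to the
#' camera is equivalent to being outside the shelter.
#'
#' @param traj A [trajectory()].
#' @return Seconds.
#' @export
time_outside_shelter <- function(traj) {
  validate_trajectory(traj)
  sum(traj$present) * frame_interval(traj)
}

#' Time spent swimming
#'
#' Counts transitions between consecutive present frames whose speed
#' (displacement over the frame interval) is at or above the configured
#' threshold; transitions never span an absence gap. Each qualifying
#' transition contributes one frame interval.
#'
#' @param traj A [trajectory()].
#' @param cfg An [activity_config()].
#' @return Seconds.
#' @export
time_swimming <- function(traj, cfg = activity_config()) {
  stopifnot(inherits(cfg, "activity_config"))
  steps <- segment_steps(traj)
  if (nrow(steps) == 0L) return(0)
  dt <- frame_interval(traj)
  sum(steps$dist / dt >= cfg$speed_threshold) * dt
}

# displacements between consecutive present frames within segments
segment_steps <- function(traj) {
  segs <- trajectory_segments(traj)
  if (nrow(segs) == 0L) return(data.frame(row = integer(), dist = numeric()))
  out <- lapply(seq_len(nrow(segs)), function(i) {
    rows <- segs$start_row[i]:segs$end_row[i]
    if (length(rows) < 2L) return(NULL)
    dx <- diff(traj$x[rows])
    dy <- diff(traj$y[rows])
    data.frame(row = rows[-1], dist = sqrt(dx^2 + dy^2))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(row = integer(), dist = numeric()) else out
}

#' Mean turning angle
#'
#' Mean absolute angle, in degrees in `[0, 180]`, between successive
#' displacement vectors over all triplets of consecutive present frames.
#' Triplets spanning an absence gap, and triplets containing a
#' zero-length displacement, are skipped. When no valid triplet exists the
#' result is `NA` (undefined, not zero).
#'
#' @param traj A [trajectory()].
#' @return Degrees, or `NA_real_` when undefined.
#' @export
mean_turning_angle <- function(traj) {
  segs <- trajectory_segments(traj)
  angles <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    rows <- segs$start_row[i]:segs$end_row[i]
    if (length(rows) < 3L) next
    dx <- diff(traj$x[rows])
    dy <- diff(traj$y[rows])
    len <- sqrt(dx^2 + dy^2)
    for (j in seq_len(length(dx) - 1L)) {
      if (len[j] < 1e-12 || len[j + 1L] < 1e-12) next
      cosang <- (dx[j] * dx[j + 1L] + dy[j] * dy[j + 1L]) /
        (len[j] * len[j + 1L])
      angles <- c(angles, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    }
  }
  if (length(angles) == 0L) return(NA_real_)
  mean(angles)
}

#' Area of the arena covered
#'
#' Partitions the arena into square grid cells (`ceiling(width/cell)` by
#' `ceiling(height/cell)`); a cell is visited when any present-frame
#' centroid falls inside it. Points on a cell boundary belong to the cell
#' with the larger index; points on the far arena border fold into the last
#' cell.
#'
#' @param traj A [trajectory()].
#' @param cfg An [activity_config()].
#' @return A list with `cells_visited` (count) and `area_fraction`
#'   (visited / total cells, in `[0, 1]`).
#' @export
area_covered <- function(traj, cfg = activity_config()) {
  stopifnot(inherits(cfg, "activity_config"))
  validate_trajectory(traj)
  nx <- ceiling(cfg$arena$width / cfg$grid_cell)
  ny <- ceiling(cfg$arena$height / cfg$grid_cell)
  pres <- traj$present
  if (!any(pres)) {
    return(list(cells_visited = 0L, area_fraction = 0))
  }
  ix <- pmin(floor(traj$x[pres] / cfg$grid_cell), nx - 1)
  iy <- pmin(floor(traj$y[pres] / cfg$grid_cell), ny - 1)
  visited <- length(unique(ix * ny + iy))
  list(cells_visited = visited, area_fraction = visited / (nx * ny))
}

#' Minimum distance of approach to the novel object
#'
#' @param traj A [trajectory()].
#' @param cfg An [exploration_config()].
#' @return Pixels, or `NA_real_` when no frame is present.
#' @export
min_object_distance <- function(traj, cfg) {
  stopifnot(inherits(cfg, "exploration_config"))
  validate_trajectory(traj)
  pres <- traj$present
  if (!any(pres)) return(NA_real_)
  min(sqrt((traj$x[pres] - cfg$object_centroid[1])^2 +
           (traj$y[pres] - cfg$object_centroid[2])^2))
}

#' Time spent near the novel object
#'
#' Present frames whose centroid lies within `near_radius` of the object
#' centroid (inclusive), times the frame interval.
#'
#' @param traj A [trajectory()].
#' @param cfg An [exploration_config()].
#' @return Seconds.
#' @export
time_near_object <- function(traj, cfg) {
  stopifnot(inherits(cfg, "exploration_config"))
  validate_trajectory(traj)
  pres <- traj$present
  if (!any(pres)) return(0)
  d <- sqrt((traj$x[pres] - cfg$object_centroid[1])^2 +
            (traj$y[pres] - cfg$object_centroid[2])^2)
  sum(d <= cfg$near_radius) * frame_interval(traj)
}

#' Activity (open-field) metric bundle
#'
#' Time outside the shelter, time swimming, mean turning angle, and arena
#' area covered, for one video.
#'
#' @param traj A [trajectory()].
#' @param cfg An [activity_config()].
#' @return A one-row data frame: `time_outside_s`, `time_swimming_s`,
#'   `mean_turning_deg` (`NA` when undefined), `cells_visited`,
#'   `area_fraction`.
#' @export
activity_metrics <- function(traj, cfg = activity_config()) {
  area <- area_covered(traj, cfg)
  data.frame(time_outside_s = time_outside_shelter(traj),
             time_swimming_s = time_swimming(traj, cfg),
             mean_turning_deg = mean_turning_angle(traj),
             cells_visited = area$cells_visited,
             area_fraction = area$area_fraction)
}

#' Exploration (novel-object) metric bundle
#'
#' Time outside the shelter, minimum distance of approach to the object,
#' and time spent within the near radius, for one video.
#'
#' @param traj A [trajectory()].
#' @param cfg An [exploration_config()].
#' @return A one-row data frame: `time_outside_s`,
#'   `min_object_distance_px` (`NA` when no frame is present),
#'   `time_near_object_s`.
#' @export
exploration_metrics <- function(traj, cfg) {
  data.frame(time_outside_s = time_outside_shelter(traj),
             min_object_distance_px = min_object_distance(traj, cfg),
             time_near_object_s = time_near_object(traj, cfg))
}
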