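# Per-frame series types: detector output and manual presence annotation.
#
# Both are stored as data frames with a `frame_index` column in units of
# frames (the pipeline runs at one analysed frame per second by default;
# `frame_interval` converts frame counts to seconds). Frame indices are
# 0-based integer frame numbers and must be strictly increasing.

#' Detection series
#'
#' Per-frame output of the fish detector for one video: the classification
#' probability of the single most reliable object proposal and its bounding
#' box. A box is recorded for every frame, including low-probability ones.
#'
#' @param frame_index Integer frame numbers (0-based), strictly increasing.
#' @param probability Class probabilities in `[0, 1]`.
#' @param box A data frame of bounding boxes, one row per frame (columns
#'   `x_min`, `y_min`, `x_max`, `y_max`).
#' @param video_id Video label.
#' @param frame_interval Seconds between analysed frames (default 1).
#'
#' @return A data frame with columns `frame_index`, `probability`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, class `detection_series`, and attributes
#'   `video_id` and `frame_interval`.
#' @examples
#' detection_series(0:2, c(0.9, 0.2, 0.7),
#'                  bounding_box(c(0, 5, 10), 0, c(40, 45, 50), 25),
#'                  video_id = "v1")
#' @export
detection_series <- function(frame_index, probability, box,
                             video_id = "video", frame_interval = 1) {
  n <- length(frame_index)
  if (n == 0L) {
    box <- data.frame(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric())
  }
  if (length(probability) != n || nrow(box) != n) {
    stop("frame_index, probability and box must have one entry per frame",
         call. = FALSE)
  }
  out <- data.frame(frame_index = as.integer(frame_index),
                    probability = as.numeric(probability),
                    x_min = as.numeric(box$x_min),
                    y_min = as.numeric(box$y_min),
                    x_max = as.numeric(box$x_max),
                    y_max = as.numeric(box$y_max))
  attr(out, "video_id") <- video_id
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("detection_series", "data.frame")
  validate_detection_series(out)
}

validate_detection_series <- function(series) {
  fi <- series$frame_index
  if (anyNA(fi) || (length(fi) && any(fi < 0))) {
    stop("frame_index must be non-negative and non-missing", call. = FALSE)
  }
  if (length(fi) > 1L && any(diff(fi) <= 0)) {
    bad <- which(diff(fi) <= 0)[1] + 1L
    stop(sprintf("frame_index must be strictly increasing (violated at row %d)",
                 bad), call. = FALSE)
  }
  p <- series$probability
  if (anyNA(p) || (length(p) && (any(p < 0) || any(p > 1)))) {
    bad <- which(is.na(p) | p < 0 | p > 1)[1]
    stop(sprintf("probability outside [0, 1] at row %d", bad), call. = FALSE)
  }
  validate_boxes(series)
  invisible(series)
}

#' Annotation series
#'
#' Human-labelled binary presence per frame: 1 when the fish is visible
#' (outside the shelter), 0 when hidden. The ground truth against which the
#' detector's thresholded output is validated.
#'
#' @param frame_index Integer frame numbers (0-based), strictly increasing.
#' @param present Values in `{0, 1}`.
#' @param video_id Video label.
#' @param frame_interval Seconds between frames (default 1).
#'
#' @return A data frame with columns `frame_index`, `present`, class
#'   `annotation_series`, attributes `video_id` and `frame_interval`.
#' @examples
#' annotation_series(0:3, c(0, 1, 1, 0))
#' @export
annotation_series <- function(frame_index, present, video_id = "video",
                              frame_interval = 1) {
  if (length(frame_index) != length(present)) {
    stop("frame_index and present must have equal length", call. = FALSE)
  }
  out <- data.frame(frame_index = as.integer(frame_index),
                    present = as.integer(present))
  attr(out, "video_id") <- video_id
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("annotation_series", "data.frame")
  validate_annotation_series(out)
}

validate_annotation_series <- function(series) {
  fi <- series$frame_index
  if (anyNA(fi) || (length(fi) && any(fi < 0))) {
    stop("frame_index must be non-negative and non-missing", call. = FALSE)
  }
  if (length(fi) > 1L && any(diff(fi) <= 0)) {
    bad <- which(diff(fi) <= 0)[1] + 1L
    stop(sprintf("frame_index must be strictly increasing (violated at row %d)",
                 bad), call. = FALSE)
  }
  v <- series$present
  if (anyNA(v) || !all(v %in% c(0L, 1L))) {
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))[1]
    stop(sprintf("presence value not in {0, 1} at row %d", bad),
         call. = FALSE)
  }
  invisible(series)
}

#' Video id and frame interval accessors
#' @param x A detection, annotation or trajectory object.
#' @return The video label, or the frame spacing in seconds.
#' @export
video_id <- function(x) attr(x, "video_id")

#' @rdname video_id
#' @export
frame_interval <- function(x) attr(x, "frame_interval") %||% 1

#' Align a detection series with a manual annotation series
#'
#' Pairs the detector's per-frame probability with the manual presence value
#' so the two time series can be compared frame by frame.
#'
#' Modes: `"strict"` requires equal lengths and identical frame indices;
#' `"truncate"` pairs up to the shorter series (with a warning);
#' `"fill"` uses the annotation frames as reference and treats any frame
#' missing from the detections as probability 0 with no box — the detector
#' produced no usable proposal, which is evidence of absence.
#'
#' @param detections A [detection_series()].
#' @param annotations An [annotation_series()] for the same video.
#' @param mode One of `"strict"`, `"truncate"`, `"fill"`.
#' @return A data frame with columns `frame_index`, `probability`,
#'   `present`.
#' @export
align_series <- function(detections, annotations,
                         mode = c("strict", "truncate", "fill")) {
  mode <- match.arg(mode)
  validate_detection_series(detections)
  validate_annotation_series(annotations)
  vd <- video_id(detections)
  va <- video_id(annotations)
  if (!is.null(vd) && !is.null(va) && !identical(vd, va)) {
    stop(sprintf("video_id mismatch: detections '%s' vs annotations '%s'",
                 vd, va), call. = FALSE)
  }
  nd <- nrow(detections)
  na <- nrow(annotations)
  if (mode == "strict") {
    if (nd != na) {
      stop(sprintf(
        "alignment error: %d detection frames vs %d annotation frames",
        nd, na), call. = FALSE)
    }
    if (!all(detections$frame_index == annotations$frame_index)) {
      stop("alignment error: frame indices differ", call. = FALSE)
    }
    return(data.frame(frame_index = annotations$frame_index,
                      probability = detections$probability,
                      present = annotations$present))
  }
  if (mode == "truncate") {
    n <- min(nd, na)
    if (nd != na) {
      warning(sprintf("aligning by truncation: %d vs %d frames, keeping %d",
                      nd, na, n), call. = FALSE)
    }
    return(data.frame(frame_index = annotations$frame_index[seq_len(n)],
                      probability = detections$probability[seq_len(n)],
                      present = annotations$present[seq_len(n)]))
  }
  # fill: annotation frames are the reference
  idx <- match(annotations$frame_index, detections$frame_index)
  prob <- detections$probability[idx]
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(sprintf(
      "%d annotated frame(s) missing from detections; treated as probability 0",
      n_missing))
    prob[is.na(idx)] <- 0
  }
  data.frame(frame_index = annotations$frame_index,
             probability = prob,
             present = annotations$present)
}
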