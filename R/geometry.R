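# Arena geometry and bounding-box primitives.
#
# Coordinates are image pixel coordinates: origin at the top-left corner,
# x increasing rightward, y increasing downward, matching the convention of
# the VOC/LabelImg annotations the pipeline consumes.

#' Arena geometry
#'
#' Describes the experimental arena as seen by the camera: the frame size in
#' pixels, optionally the shelter region (an axis-aligned rectangle the fish
#' is invisible inside) and the centroid of the novel object used in
#' exploration tests.
#'
#' @param width,height Frame size in pixels. Defaults are the recording
#'   frame size, 1280 x 768.
#' @param shelter_region Optional rectangle `c(x_min, y_min, x_max, y_max)`
#'   in pixels; must lie within the frame.
#' @param object_centroid Optional point `c(x, y)` in pixels; must lie
#'   within the frame. Only needed for exploration (novel-object) tests.
#'
#' @return An object of class `arena_geometry`.
#' @examples
#' arena_geometry()
#' arena_geometry(object_centroid = c(900, 400))
#' @export
arena_geometry <- function(width = 1280, height = 768,
                           shelter_region = NULL, object_centroid = NULL) {
  assert_scalar_number(width, "width", lower = .Machine$double.eps)
  assert_scalar_number(height, "height", lower = .Machine$double.eps)
  if (!is.null(shelter_region)) {
    shelter_region <- as.numeric(shelter_region)
    if (length(shelter_region) != 4L) {
      stop("`shelter_region` must be c(x_min, y_min, x_max, y_max)",
           call. = FALSE)
    }
    if (shelter_region[1] > shelter_region[3] ||
        shelter_region[2] > shelter_region[4] ||
        any(shelter_region < 0) ||
        shelter_region[3] > width || shelter_region[4] > height) {
      stop("`shelter_region` must be a valid rectangle inside the arena",
           call. = FALSE)
    }
    names(shelter_region) <- c("x_min", "y_min", "x_max", "y_max")
  }
  if (!is.null(object_centroid)) {
    object_centroid <- as.numeric(object_centroid)
    if (length(object_centroid) != 2L ||
        object_centroid[1] < 0 || object_centroid[1] > width ||
        object_centroid[2] < 0 || object_centroid[2] > height) {
      stop("`object_centroid` must be a point c(x, y) inside the arena",
           call. = FALSE)
    }
    names(object_centroid) <- c("x", "y")
  }
  structure(
    list(width = width, height = height,
         shelter_region = shelter_region, object_centroid = object_centroid),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf("<arena_geometry> %g x %g px\n", x$width, x$height))
  if (!is.null(x$shelter_region)) {
    cat(sprintf("  shelter: [%g, %g] x [%g, %g]\n",
                x$shelter_region[1], x$shelter_region[3],
                x$shelter_region[2], x$shelter_region[4]))
  }
  if (!is.null(x$object_centroid)) {
    cat(sprintf("  object centroid: (%g, %g)\n",
                x$object_centroid[1], x$object_centroid[2]))
  }
  invisible(x)
}

#' Bounding boxes
#'
#' Constructs a table of axis-aligned bounding boxes in pixel coordinates
#' (origin top-left, corners stored as LabelImg writes them). All arguments
#' are recycled to a common length.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates in pixels; each
#'   `x_min <= x_max`, `y_min <= y_max`, all non-negative.
#' @return A data frame with columns `x_min`, `y_min`, `x_max`, `y_max` and
#'   class `bounding_box`.
#' @examples
#' bounding_box(10, 20, 110, 220)
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  box <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                    x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(box)
  class(box) <- c("bounding_box", "data.frame")
  box
}

validate_boxes <- function(box) {
  needed <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(needed %in% names(box))) {
    stop("boxes need columns x_min, y_min, x_max, y_max", call. = FALSE)
  }
  bad <- which(box$x_min > box$x_max | box$y_min > box$y_max)
  if (length(bad)) {
    stop(sprintf("invalid box at row %d: min corner exceeds max corner",
                 bad[1]), call. = FALSE)
  }
  neg <- which(box$x_min < 0 | box$y_min < 0)
  if (length(neg)) {
    stop(sprintf("invalid box at row %d: negative coordinate", neg[1]),
         call. = FALSE)
  }
  invisible(box)
}

#' Bounding-box centroid
#'
#' The per-frame fish position is the midpoint of its bounding box.
#'
#' @param box A data frame of boxes (see [bounding_box()]).
#' @return A data frame with real-valued columns `x`, `y`, one row per box.
#' @examples
#' bbox_centroid(bounding_box(0, 0, 10, 10)) # (5, 5)
#' @export
bbox_centroid <- function(box) {
  validate_boxes(box)
  data.frame(x = (box$x_min + box$x_max) / 2,
             y = (box$y_min + box$y_max) / 2)
}

#' Box side lengths
#'
#' Pools the widths and heights of a set of boxes into one vector (two side
#' lengths per box); the positioning success threshold is the mean of this
#' pool.
#'
#' @param box A data frame of boxes.
#' @return Numeric vector of length `2 * nrow(box)`.
#' @export
box_side_lengths <- function(box) {
  validate_boxes(box)
  c(box$x_max - box$x_min, box$y_max - box$y_min)
}
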