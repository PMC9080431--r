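# Readers and writers for the pipeline's tabular formats and for PASCAL VOC
# bounding-box XML (the LabelImg dialect).
#
# Tabular dialect: comma-separated, mandatory header row, UTF-8, '.' decimal
# separator. Numeric fields are written with full double precision so that
# read(write(x)) reproduces x exactly.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == trunc(v) && abs(v) < 2^53) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}

#' Read and write detection tables
#'
#' Detection CSVs carry one row per analysed frame with columns `video_id`,
#' `frame_index`, `probability`, `x_min`, `y_min`, `x_max`, `y_max`.
#' Validation failures name the offending row.
#'
#' @param path Path to a CSV file.
#' @param frame_interval Seconds between analysed frames (default 1).
#' @return `read_detections()` returns a [detection_series()] (or a list of
#'   them, named by video, when the file holds several videos);
#'   `write_detections()` invisibly returns `path`.
#' @export
read_detections <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_index", "probability", "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in needed) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad)) {
      stop(sprintf("%s: cannot parse %s at line %d", path, col, bad[1] + 1L),
           call. = FALSE)
    }
    raw[[col]] <- val
  }
  ids <- if ("video_id" %in% names(raw)) raw$video_id else "video"
  build <- function(df, id) {
    detection_series(df$frame_index, df$probability,
                     data.frame(x_min = df$x_min, y_min = df$y_min,
                                x_max = df$x_max, y_max = df$y_max),
                     video_id = id, frame_interval = frame_interval)
  }
  if (length(unique(ids)) <= 1L) {
    build(raw, if (nrow(raw)) ids[1] else "video")
  } else {
    split_df <- split(raw, raw$video_id)
    lapply(stats::setNames(names(split_df), names(split_df)),
           function(id) build(split_df[[id]], id))
  }
}

#' @rdname read_detections
#' @param series A [detection_series()].
#' @export
write_detections <- function(series, path) {
  validate_detection_series(series)
  out <- data.frame(
    video_id = rep(video_id(series) %||% "video", nrow(series)),
    frame_index = series$frame_index,
    probability = fmt_num(series$probability),
    x_min = fmt_num(series$x_min), y_min = fmt_num(series$y_min),
    x_max = fmt_num(series$x_max), y_max = fmt_num(series$y_max),
    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    out <- out[0, , drop = FALSE]
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write manual annotation tables
#'
#' Annotation CSVs carry columns `video_id` (optional), `frame_index` and
#' `present` (0 or 1; 1 means the fish is visible, i.e. outside the
#' shelter).
#'
#' @param path Path to a CSV file.
#' @param frame_interval Seconds between frames (default 1).
#' @return `read_annotations()` returns an [annotation_series()] (or a
#'   named list of them for a multi-video file); `write_annotations()`
#'   invisibly returns `path`.
#' @export
read_annotations <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame_index", "present")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ids <- if ("video_id" %in% names(raw)) raw$video_id else "video"
  build <- function(df, id) {
    annotation_series(df$frame_index, df$present, video_id = id,
                      frame_interval = frame_interval)
  }
  if (length(unique(ids)) <= 1L) {
    build(raw, if (nrow(raw)) ids[1] else "video")
  } else {
    split_df <- split(raw, raw$video_id)
    lapply(stats::setNames(names(split_df), names(split_df)),
           function(id) build(split_df[[id]], id))
  }
}

#' @rdname read_annotations
#' @param series An [annotation_series()].
#' @export
write_annotations <- function(series, path) {
  validate_annotation_series(series)
  out <- data.frame(
    video_id = rep(video_id(series) %||% "video", nrow(series)),
    frame_index = series$frame_index,
    present = series$present)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse PASCAL VOC bounding-box XML
#'
#' Reads manually drawn boxes from PASCAL VOC annotation XML as written by
#' LabelImg: one file per image, each `<object>` holding a `<bndbox>` with
#' integer `xmin`/`ymin`/`xmax`/`ymax` tags. Coordinates are taken verbatim.
#'
#' @param path A single `.xml` file, or a directory containing such files.
#' @return A data frame with columns `image_id` (the annotated image's
#'   filename without extension), `x_min`, `y_min`, `x_max`, `y_max`, one
#'   row per object in document order. Zero-object files contribute no rows.
#' @export
parse_voc_boxes <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
    out <- lapply(files, parse_voc_boxes)
    return(do.call(rbind, c(out, list(empty_voc_df()))))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  image_id <- if (is.na(fname) || !nzchar(fname)) {
    sub("\\.xml$", "", basename(path))
  } else {
    sub("\\.[^.]*$", "", basename(fname))
  }
  objects <- xml2::xml_find_all(doc, ".//object")
  if (length(objects) == 0L) return(empty_voc_df())
  rows <- lapply(objects, function(obj) {
    bnd <- xml2::xml_find_first(obj, "./bndbox")
    if (is.na(bnd) || inherits(bnd, "xml_missing")) {
      stop(sprintf("%s: <object> without <bndbox>", path), call. = FALSE)
    }
    coord <- function(tag) {
      node <- xml2::xml_find_first(bnd, paste0("./", tag))
      if (inherits(node, "xml_missing")) {
        stop(sprintf("%s: <bndbox> missing <%s>", path, tag), call. = FALSE)
      }
      as.numeric(xml2::xml_text(node))
    }
    data.frame(image_id = image_id,
               x_min = coord("xmin"), y_min = coord("ymin"),
               x_max = coord("xmax"), y_max = coord("ymax"))
  })
  out <- do.call(rbind, rows)
  validate_boxes(out)
  out
}

empty_voc_df <- function() {
  data.frame(image_id = character(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric())
}

#' Split VOC image ids into video id and frame index
#'
#' Manual boxes are keyed to frames through the annotated image's filename,
#' by default `<video_id>_<frame_index>`.
#'
#' @param image_id Character vector of image ids (filename stems).
#' @param pattern A regex with two capture groups (video id, frame index).
#' @return A data frame with columns `video_id` and `frame_index`.
#' @export
parse_frame_key <- function(image_id, pattern = "^(.*)_([0-9]+)$") {
  m <- regmatches(image_id, regexec(pattern, image_id))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) {
    stop(sprintf("image id '%s' does not match pattern '%s'",
                 image_id[bad[1]], pattern), call. = FALSE)
  }
  data.frame(video_id = vapply(m, `[`, character(1), 2L),
             frame_index = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Write boxes as PASCAL VOC XML files
#'
#' One file per image id, LabelImg-style layout. Mainly used to build
#' synthetic manual-annotation fixtures.
#'
#' @param boxes Data frame with columns `image_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @param dir Output directory (created if needed).
#' @param width,height Image size recorded in the `<size>` element.
#' @return Invisibly, the paths written.
#' @export
write_voc_boxes <- function(boxes, dir, width = 1280, height = 768) {
  validate_boxes(boxes)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(boxes, boxes$image_id), function(df) {
    id <- df$image_id[1]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(id, ".jpg"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", as.character(as.integer(width)))
    xml2::xml_add_child(size, "height", as.character(as.integer(height)))
    xml2::xml_add_child(size, "depth", "3")
    for (i in seq_len(nrow(df))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", "fish")
      bnd <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bnd, "xmin", sprintf("%d", as.integer(round(df$x_min[i]))))
      xml2::xml_add_child(bnd, "ymin", sprintf("%d", as.integer(round(df$y_min[i]))))
      xml2::xml_add_child(bnd, "xmax", sprintf("%d", as.integer(round(df$x_max[i]))))
      xml2::xml_add_child(bnd, "ymax", sprintf("%d", as.integer(round(df$y_max[i]))))
    }
    p <- file.path(dir, paste0(id, ".xml"))
    xml2::write_xml(doc, p)
    p
  }, character(1))
  invisible(unname(paths))
}
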