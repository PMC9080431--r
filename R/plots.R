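# Diagnostic figures. All plots are optional side outputs of the pipeline;
# nothing downstream depends on them.

#' Presence-validation plot for one video
#'
#' Manual presence as shaded bands with the detector's per-frame
#' probability overlaid as points, and the threshold as a horizontal line.
#'
#' @param detections A [detection_series()].
#' @param annotations An [annotation_series()].
#' @param tau Threshold to draw.
#' @return A ggplot object.
#' @export
plot_presence_validation <- function(detections, annotations, tau = 0.5) {
  aligned <- align_series(detections, annotations, mode = "truncate")
  aligned$manual <- factor(aligned$present, levels = c(0, 1),
                           labels = c("absent", "present"))
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$frame_index)) +
    ggplot2::geom_tile(ggplot2::aes(y = 0.5, height = 1,
                                    fill = .data$manual),
                       width = 1, alpha = 0.3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$probability), size = 0.3) +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_fill_manual(values = c(absent = "grey70",
                                          present = "steelblue"),
                               name = "manual") +
    ggplot2::labs(x = "frame (s)", y = "detection probability",
                  title = video_id(detections)) +
    ggplot2::theme_minimal()
}

#' Positioning error-vector plot
#'
#' Segments from each manual centroid to its predicted centroid over the
#' arena rectangle; long segments are the heavy-tailed outliers.
#'
#' @param result A `positioning_result` from [validate_positioning()].
#' @param arena An [arena_geometry()].
#' @return A ggplot object.
#' @export
plot_positioning_errors <- function(result, arena = arena_geometry()) {
  df <- result$frames
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$manual_x,
                                       y = .data$manual_y,
                                       xend = .data$pred_x,
                                       yend = .data$pred_y),
                          colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = .data$manual_x,
                                     y = .data$manual_y),
                        size = 0.4) +
    ggplot2::coord_fixed(xlim = c(0, arena$width),
                         ylim = c(arena$height, 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("positioning errors (n = %d)", result$n)) +
    ggplot2::theme_minimal()
}

#' Trajectory plot
#'
#' The fish's path over the arena, one line per present segment, with the
#' shelter region and novel object drawn when the arena defines them.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena_geometry()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, arena = arena_geometry()) {
  segs <- trajectory_segments(traj)
  df <- traj[traj$present, , drop = FALSE]
  df$segment <- NA_integer_
  for (i in seq_len(nrow(segs))) {
    rows <- segs$start_row[i]:segs$end_row[i]
    df$segment[match(rows, which(traj$present))] <- i
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$segment)) +
    ggplot2::geom_path(alpha = 0.6, colour = "steelblue") +
    ggplot2::coord_fixed(xlim = c(0, arena$width),
                         ylim = c(arena$height, 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)", title = video_id(traj)) +
    ggplot2::theme_minimal()
  if (!is.null(arena$shelter_region)) {
    sr <- arena$shelter_region
    p <- p + ggplot2::annotate("rect", xmin = sr[1], xmax = sr[3],
                               ymin = sr[2], ymax = sr[4],
                               alpha = 0.2, fill = "grey40")
  }
  if (!is.null(arena$object_centroid)) {
    oc <- arena$object_centroid
    p <- p + ggplot2::annotate("point", x = oc[1], y = oc[2],
                               shape = 4, size = 3, colour = "red")
  }
  p
}
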