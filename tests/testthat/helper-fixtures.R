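# Small builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what a test itself writes.

# a detection series with constant-size boxes centred on given points
make_detections <- function(prob, x = NULL, y = NULL, video_id = "v1",
                            half = 20) {
  n <- length(prob)
  if (is.null(x)) x <- seq(100, 100 + 10 * (n - 1), length.out = max(n, 1))
  if (is.null(y)) y <- rep(200, n)
  detection_series(seq_len(n) - 1L, prob,
                   bounding_box(x - half, y - half, x + half, y + half),
                   video_id = video_id)
}

make_annotations <- function(present, video_id = "v1") {
  annotation_series(seq_along(present) - 1L, present, video_id = video_id)
}

# trajectory visiting the given points on consecutive frames, all present
make_path_trajectory <- function(x, y, video_id = "t1") {
  trajectory(seq_along(x) - 1L, TRUE, x, y, video_id = video_id)
}

# noiseless detector: probability exactly 1 when visible, 0 when hidden,
# no jitter, no outliers
noiseless_noise <- function(seed = 1L) {
  noise_params(present_prob = 1, absent_prob = 0, jitter_sigma = 0,
               outlier_prob = 0, seed = seed)
}

# one fully-visible synthetic video (fish never enters the shelter)
all_visible_params <- function(duration, seed = 1L, step_sigma = 20,
                               persistence = 0, border_margin = 80) {
  simulation_params(duration = duration, p_exit = 1, p_enter = 0,
                    step_sigma = step_sigma, persistence = persistence,
                    start_state = "visible", border_margin = border_margin,
                    shelter_anchor = c(640, 384), seed = seed)
}

voc_xml_example <- function() {
  paste0(
    "<annotation><filename>v1_42.jpg</filename>",
    "<size><width>1280</width><height>768</height><depth>3</depth></size>",
    "<object><name>fish</name><bndbox>",
    "<xmin>10</xmin><ymin>20</ymin><xmax>110</xmax><ymax>220</ymax>",
    "</bndbox></object></annotation>")
}
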