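# Domain types, tabular readers/writers, VOC XML parsing, alignment.

test_that("detection CSV round-trips exactly, including boundary values", {
  s <- make_detections(c(0, 1, 0.123456789012345, 1 / 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(s, path)
  back <- read_detections(path)
  expect_identical(back$frame_index, s$frame_index)
  expect_identical(back$probability, s$probability)
  expect_identical(back$x_min, s$x_min)
  expect_identical(back$y_max, s$y_max)
  expect_identical(video_id(back), "v1")

  # empty series -> header-only file -> empty series
  empty <- detection_series(integer(), numeric(),
                            data.frame(x_min = numeric(), y_min = numeric(),
                                       x_max = numeric(), y_max = numeric()))
  write_detections(empty, path)
  expect_equal(nrow(read_detections(path)), 0)
})

test_that("detection reader rejects invalid rows with a located error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("video_id,frame_index,probability,x_min,y_min,x_max,y_max",
               "v1,0,0.5,0,0,10,10",
               "v1,1,1.2,0,0,10,10"), path)
  expect_error(read_detections(path), "probability.*row 2")

  writeLines(c("video_id,frame_index,probability,x_min,y_min,x_max,y_max",
               "v1,3,0.5,0,0,10,10",
               "v1,2,0.5,0,0,10,10"), path)
  expect_error(read_detections(path), "strictly increasing")

  writeLines(c("video_id,frame_index,probability,x_min,y_min,x_max,y_max",
               "v1,0,abc,0,0,10,10"), path)
  expect_error(read_detections(path), "line 2")
})

test_that("annotation CSV round-trips and rejects non-binary values", {
  a <- make_annotations(c(0, 1, 1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(a, path)
  back <- read_annotations(path)
  expect_identical(back$present, c(0L, 1L, 1L, 0L))

  writeLines(c("video_id,frame_index,present", "v1,0,2"), path)
  expect_error(read_annotations(path), "not in \\{0, 1\\}")

  # a long series survives intact
  long <- make_annotations(rep(c(0L, 1L), 1800))
  write_annotations(long, path)
  expect_equal(nrow(read_annotations(path)), 3600)
})

test_that("VOC XML parsing maps fields verbatim and keeps document order", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(voc_xml_example(), path)
  boxes <- parse_voc_boxes(path)
  expect_equal(nrow(boxes), 1)
  expect_equal(boxes$image_id, "v1_42")
  expect_equal(unlist(boxes[1, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE),
               c(10, 20, 110, 220))

  key <- parse_frame_key(boxes$image_id)
  expect_equal(key$video_id, "v1")
  expect_equal(key$frame_index, 42L)

  # two objects, document order; zero objects -> empty frame
  two <- sub("</annotation>", paste0(
    "<object><name>fish</name><bndbox><xmin>1</xmin><ymin>2</ymin>",
    "<xmax>3</xmax><ymax>4</ymax></bndbox></object></annotation>"),
    voc_xml_example())
  writeLines(two, path)
  boxes2 <- parse_voc_boxes(path)
  expect_equal(boxes2$x_min, c(10, 1))
  writeLines("<annotation><filename>e_0.jpg</filename></annotation>", path)
  expect_equal(nrow(parse_voc_boxes(path)), 0)
})

test_that("VOC parsing is insensitive to whitespace and bndbox tag order", {
  path <- withr::local_tempfile(fileext = ".xml")
  scrambled <- paste0(
    "<annotation>\n  <filename>v1_42.jpg</filename>\n  <object>\n",
    "    <bndbox>\n      <ymax>220</ymax>\n      <xmin>10</xmin>\n",
    "      <ymin>20</ymin>\n      <xmax>110</xmax>\n    </bndbox>\n",
    "  </object>\n</annotation>")
  writeLines(scrambled, path)
  expect_equal(parse_voc_boxes(path)[, -1],
               data.frame(x_min = 10, y_min = 20, x_max = 110, y_max = 220))
})

test_that("VOC parsing flags missing bndbox and inverted corners", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<annotation><object><name>fish</name></object></annotation>",
             path)
  expect_error(parse_voc_boxes(path), "bndbox")
  writeLines(paste0(
    "<annotation><object><bndbox><xmin>50</xmin><ymin>0</ymin>",
    "<xmax>10</xmax><ymax>5</ymax></bndbox></object></annotation>"), path)
  expect_error(parse_voc_boxes(path), "min corner exceeds max")
})

test_that("write_voc_boxes round-trips through parse_voc_boxes", {
  dir <- withr::local_tempdir()
  boxes <- data.frame(image_id = c("v1_0", "v1_0", "v2_7"),
                      x_min = c(10, 200, 5), y_min = c(20, 100, 6),
                      x_max = c(110, 260, 45), y_max = c(220, 150, 56))
  write_voc_boxes(boxes, dir)
  back <- parse_voc_boxes(dir)
  back <- back[order(back$image_id, back$x_min), ]
  orig <- boxes[order(boxes$image_id, boxes$x_min), ]
  expect_equal(back$x_min, orig$x_min)
  expect_equal(back$y_max, orig$y_max)
})

test_that("bbox_centroid is the box midpoint and lies inside its box", {
  expect_equal(bbox_centroid(bounding_box(0, 0, 10, 10)),
               data.frame(x = 5, y = 5))
  expect_equal(bbox_centroid(bounding_box(3, 4, 3, 4)),
               data.frame(x = 3, y = 4))
  expect_equal(bbox_centroid(bounding_box(100, 200, 300, 400)),
               data.frame(x = 200, y = 300))
  # property: centroid inside (or on the border of) the box
  set.seed(11)
  b <- bounding_box(runif(50, 0, 500), runif(50, 0, 300),
                    runif(50, 500, 1280), runif(50, 300, 768))
  cen <- bbox_centroid(b)
  expect_true(all(cen$x >= b$x_min & cen$x <= b$x_max))
  expect_true(all(cen$y >= b$y_min & cen$y <= b$y_max))
})

test_that("alignment modes behave as specified", {
  d <- make_detections(c(0.9, 0.1, 0.8))
  a <- make_annotations(c(1, 0, 1))
  aligned <- align_series(d, a, mode = "strict")
  expect_equal(nrow(aligned), 3)
  expect_equal(aligned$probability, d$probability)

  a2 <- make_annotations(c(1, 0))
  expect_error(align_series(d, a2, mode = "strict"), "3.*2")
  expect_warning(tr <- align_series(d, a2, mode = "truncate"), "truncation")
  expect_equal(nrow(tr), 2)

  # fill mode: annotated frames missing from detections get probability 0
  d_gap <- detection_series(c(0L, 2L), c(0.9, 0.8),
                            bounding_box(c(0, 0), 0, c(40, 40), 25),
                            video_id = "v1")
  expect_message(fl <- align_series(d_gap, a, mode = "fill"), "probability 0")
  expect_equal(fl$probability, c(0.9, 0, 0.8))

  b <- make_annotations(c(1, 0, 1), video_id = "other")
  expect_error(align_series(d, b), "video_id mismatch")
})

test_that("type constructors enforce their invariants", {
  expect_error(detection_series(0:1, c(0.5, 1.2),
                                bounding_box(c(0, 0), 0, c(1, 1), 1)),
               "probability")
  expect_error(annotation_series(0:1, c(0, 2)), "\\{0, 1\\}")
  expect_error(bounding_box(10, 0, 5, 5), "min corner")
  expect_error(bounding_box(-1, 0, 5, 5), "negative")
  expect_error(arena_geometry(shelter_region = c(0, 0, 2000, 100)),
               "shelter_region")
  expect_error(arena_geometry(object_centroid = c(-5, 10)),
               "object_centroid")
})
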