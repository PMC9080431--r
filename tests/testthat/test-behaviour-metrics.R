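# Trajectories from thresholded detections and the activity/exploration
# metric set, checked against geometric closed forms and the simulator's
# ground truth.

test_that("build_trajectory thresholds presence and decomposes into runs", {
  d <- make_detections(c(1, 1, 0, 1))
  traj <- build_trajectory(d, 0.5)
  expect_equal(traj$present, c(TRUE, TRUE, FALSE, TRUE))
  segs <- trajectory_segments(traj)
  expect_equal(segs$n_frames, c(2L, 1L))
  expect_true(is.na(traj$x[3]))

  all_in <- build_trajectory(make_detections(rep(1, 5)), 0.5)
  expect_equal(nrow(trajectory_segments(all_in)), 1)

  # frame gaps break segments even when both sides are present
  gap <- detection_series(c(0L, 1L, 5L, 6L), rep(0.9, 4),
                          bounding_box(rep(0, 4), 0, rep(40, 4), 25))
  expect_equal(trajectory_segments(build_trajectory(gap, 0.5))$n_frames,
               c(2L, 2L))
})

test_that("time outside the shelter counts present frames", {
  traj <- make_path_trajectory(1:100, rep(1, 100))
  expect_equal(time_outside_shelter(traj), 100)
  none <- trajectory(0:9, FALSE, NA_real_, NA_real_)
  expect_equal(time_outside_shelter(none), 0)
  f <- make_annotations(rep(c(1, 0), 50))
  traj2 <- trajectory(f$frame_index, f$present == 1,
                      ifelse(f$present == 1, 10, NA),
                      ifelse(f$present == 1, 10, NA))
  expect_equal(time_outside_shelter(traj2), 50)
})

test_that("time swimming applies the speed threshold within segments", {
  cfg <- activity_config(speed_threshold = 5)
  still <- make_path_trajectory(rep(7, 20), rep(7, 20))
  expect_equal(time_swimming(still, cfg), 0)

  # threshold 0: every transition of a k-frame segment counts
  cfg0 <- activity_config(speed_threshold = 0)
  seg <- make_path_trajectory(1:12, rep(0, 12))
  expect_equal(time_swimming(seg, cfg0), 11)

  # alternating 10 px and 2 px steps: half the transitions qualify
  x <- cumsum(c(0, rep(c(10, 2), 10)))
  alt <- make_path_trajectory(x, rep(0, length(x)))
  expect_equal(time_swimming(alt, cfg), 10)

  # a gap between two fast frames must not create a transition
  gapped <- trajectory(c(0L, 1L, 3L, 4L), c(TRUE, TRUE, TRUE, TRUE),
                       c(0, 10, 100, 110), rep(0, 4))
  expect_equal(time_swimming(gapped, cfg), 2)
})

test_that("mean turning angle matches polygon exterior angles", {
  collinear <- make_path_trajectory(seq(0, 90, by = 10), rep(5, 10))
  expect_equal(mean_turning_angle(collinear), 0)

  square <- make_path_trajectory(c(0, 10, 10, 0, 0, 10),
                                 c(0, 0, 10, 10, 0, 0))
  expect_equal(mean_turning_angle(square), 90)

  hexagon <- make_path_trajectory(100 + 50 * cos(2 * pi * (0:7) / 6),
                                  100 + 50 * sin(2 * pi * (0:7) / 6))
  expect_equal(mean_turning_angle(hexagon), 60)

  # zero displacements are skipped, not averaged in as zero angles
  stall <- make_path_trajectory(c(0, 10, 20, 20, 30, 40), rep(0, 6))
  expect_equal(mean_turning_angle(stall), 0)
  turn <- make_path_trajectory(c(0, 10, 10, 10, 0), c(0, 0, 0, 10, 10))
  expect_equal(mean_turning_angle(turn), 90) # only the last pair is valid

  # no valid triplet -> explicitly missing
  expect_true(is.na(mean_turning_angle(make_path_trajectory(c(1, 2),
                                                            c(1, 1)))))
  expect_true(is.na(mean_turning_angle(make_path_trajectory(rep(3, 5),
                                                            rep(3, 5)))))
})

test_that("area coverage uses the grid partition with boundary-up rule", {
  cfg <- activity_config(grid_cell = 32)
  one <- make_path_trajectory(rep(100, 50), rep(100, 50))
  a1 <- area_covered(one, cfg)
  expect_equal(a1$cells_visited, 1L)

  none <- trajectory(0:4, FALSE, NA_real_, NA_real_)
  expect_equal(area_covered(none, cfg)$area_fraction, 0)

  # every cell centre of the 40 x 24 grid -> full coverage
  centers <- expand.grid(x = 32 * (0:39) + 16, y = 32 * (0:23) + 16)
  full <- make_path_trajectory(centers$x, centers$y)
  af <- area_covered(full, cfg)
  expect_equal(af$cells_visited, 960L)
  expect_equal(af$area_fraction, 1.0)

  # boundary points fall into the larger-index cell; the far wall folds in
  edge <- make_path_trajectory(c(32, 1280), c(0, 768))
  expect_equal(area_covered(edge, cfg)$cells_visited, 2L)
})

test_that("object approach metrics follow the geometry", {
  cfg <- exploration_config(object_centroid = c(640, 284))
  pass <- make_path_trajectory(seq(0, 1280, by = 10), rep(384, 129))
  expect_equal(min_object_distance(pass, cfg), 100)
  expect_equal(time_near_object(pass, cfg), 1) # only the closest sample

  orbit99 <- make_path_trajectory(640 + 99 * cos(2 * pi * (0:49) / 50),
                                  384 + 99 * sin(2 * pi * (0:49) / 50))
  cfg2 <- exploration_config(object_centroid = c(640, 384),
                             near_radius = 100)
  expect_equal(time_near_object(orbit99, cfg2), 50)
  expect_equal(min_object_distance(orbit99, cfg2), 99)

  orbit101 <- make_path_trajectory(640 + 101 * cos(2 * pi * (0:49) / 50),
                                   384 + 101 * sin(2 * pi * (0:49) / 50))
  expect_equal(time_near_object(orbit101, cfg2), 0)

  at_object <- make_path_trajectory(rep(640, 10), rep(384, 10))
  expect_equal(min_object_distance(at_object, cfg2), 0)
  expect_equal(time_near_object(at_object, cfg2), 10)

  empty <- trajectory(0:3, FALSE, NA_real_, NA_real_)
  expect_true(is.na(min_object_distance(empty, cfg2)))
  expect_equal(time_near_object(empty, cfg2), 0)
})

test_that("metric bundles propagate undefined values and respect bounds", {
  empty <- trajectory(0:9, FALSE, NA_real_, NA_real_)
  am <- activity_metrics(empty)
  expect_equal(am$time_outside_s, 0)
  expect_equal(am$time_swimming_s, 0)
  expect_true(is.na(am$mean_turning_deg))
  em <- exploration_metrics(empty, exploration_config(c(640, 384)))
  expect_true(is.na(em$min_object_distance_px))
  expect_equal(em$time_near_object_s, 0)

  # swimming time never exceeds time outside; near time never exceeds it
  set.seed(31)
  for (i in 1:10) {
    v <- simulate_video(simulation_params(duration = 300, seed = i),
                        noise_params(seed = i + 100), video_id = "b")
    traj <- build_trajectory(v$detections, 0.5)
    am <- activity_metrics(traj)
    expect_lte(am$time_swimming_s, am$time_outside_s)
    em <- exploration_metrics(traj, exploration_config(c(640, 384)))
    expect_lte(em$time_near_object_s, em$time_outside_s)
    if (!is.na(am$mean_turning_deg)) {
      expect_gte(am$mean_turning_deg, 0)
      expect_lte(am$mean_turning_deg, 180)
    }
  }
})

test_that("median smoothing suppresses spikes without bridging gaps", {
  # a single-frame outlier in an otherwise straight path is removed
  x <- c(0, 10, 20, 500, 40, 50, 60)
  spiky <- make_path_trajectory(x, rep(0, 7))
  sm <- smooth_trajectory(spiky, window = 3)
  expect_equal(sm$x[4], 40) # median of (20, 500, 40)
  expect_equal(sm$x[c(1, 7)], c(0, 60)) # endpoints untouched

  # short segments (below the window) pass through unchanged
  gapped <- trajectory(c(0L, 1L, 5L, 6L, 7L), rep(TRUE, 5),
                       c(0, 100, 7, 900, 7), rep(1, 5))
  sm2 <- smooth_trajectory(gapped, window = 3)
  expect_equal(sm2$x[1:2], c(0, 100))
  expect_equal(sm2$x[4], 7) # median within the 3-frame segment only

  expect_error(smooth_trajectory(spiky, window = 4), "odd")
})

test_that("metrics are invariant under rigid translation of the scene", {
  v <- simulate_video(simulation_params(duration = 600, seed = 55),
                      noise_params(jitter_sigma = 3, outlier_prob = 0,
                                   seed = 56),
                      video_id = "t")
  traj <- build_trajectory(v$detections, 0.5)
  shift <- c(40, -25)
  shifted <- trajectory(traj$frame_index, traj$present,
                        traj$x + shift[1], traj$y + shift[2],
                        video_id = "t")
  cfg <- activity_config()
  expect_equal(time_swimming(shifted, cfg), time_swimming(traj, cfg))
  expect_equal(mean_turning_angle(shifted), mean_turning_angle(traj))
  obj <- c(500, 300)
  expect_equal(
    min_object_distance(shifted, exploration_config(obj + shift)),
    min_object_distance(traj, exploration_config(obj)))
  expect_equal(
    time_near_object(shifted, exploration_config(obj + shift)),
    time_near_object(traj, exploration_config(obj)))
})

test_that("noiseless pipeline metrics equal ground-truth metrics exactly", {
  v <- simulate_video(simulation_params(duration = 800, seed = 91),
                      noiseless_noise(), video_id = "oracle",
                      test_type = "EXP")
  traj <- build_trajectory(v$detections, 0.5)
  cfg_a <- activity_config()
  cfg_e <- exploration_config(c(900, 400))
  expect_identical(activity_metrics(traj, cfg_a),
                   activity_metrics(v$truth, cfg_a))
  expect_identical(exploration_metrics(traj, cfg_e),
                   exploration_metrics(v$truth, cfg_e))
})
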