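# The synthetic arena: occupancy chain, correlated random walk, detector
# noise. Long-run statistics are checked against their closed forms.

test_that("occupancy chain honours absorbing states and determinism", {
  p_stay_hidden <- simulation_params(duration = 200, p_exit = 0,
                                     start_state = "hidden", seed = 3)
  expect_true(all(simulate_occupancy(p_stay_hidden)$present == 0L))

  p_stay_out <- simulation_params(duration = 200, p_enter = 0,
                                  start_state = "visible", seed = 3)
  expect_true(all(simulate_occupancy(p_stay_out)$present == 1L))

  p <- simulation_params(duration = 500, seed = 42)
  expect_identical(simulate_occupancy(p), simulate_occupancy(p))
})

test_that("occupancy matches the stationary distribution of the chain", {
  # pi_visible = p_exit / (p_exit + p_enter); symmetric case -> 1/2
  p <- simulation_params(duration = 100000, p_exit = 0.5, p_enter = 0.5,
                         seed = 5)
  occ <- simulate_occupancy(p)
  frac <- mean(occ$present)
  se <- sqrt(0.25 / nrow(occ))
  expect_lt(abs(frac - 0.5), 3 * se)

  # asymmetric case, wider tolerance for chain autocorrelation
  p2 <- simulation_params(duration = 100000, p_exit = 0.3, p_enter = 0.1,
                          seed = 6)
  frac2 <- mean(simulate_occupancy(p2)$present)
  expect_lt(abs(frac2 - 0.75), 0.02)
})

test_that("occupancy bout lengths match their geometric means", {
  p <- simulation_params(duration = 200000, p_exit = 0.05, p_enter = 0.1,
                         seed = 8)
  occ <- simulate_occupancy(p)
  runs <- rle(occ$present)
  vis <- runs$lengths[runs$values == 1L]
  hid <- runs$lengths[runs$values == 0L]
  # mean bout lengths ~ 1/p_enter (visible) and 1/p_exit (hidden)
  expect_lt(abs(mean(vis) - 10) / 10, 0.1)
  expect_lt(abs(mean(hid) - 20) / 20, 0.1)
})

test_that("path: bouts restart at the anchor, zero motion stays put,
           positions stay inside the arena", {
  p <- simulation_params(duration = 300, step_sigma = 0, seed = 2)
  occ <- simulate_occupancy(p)
  traj <- simulate_path(occ, p)
  pres <- traj$present
  expect_true(any(pres))
  expect_true(all(traj$x[pres] == p$shelter_anchor[1]))
  expect_true(all(traj$y[pres] == p$shelter_anchor[2]))

  p2 <- simulation_params(duration = 2000, step_sigma = 150,
                          persistence = 0.9, seed = 9)
  traj2 <- simulate_path(simulate_occupancy(p2), p2)
  pres2 <- traj2$present
  expect_true(all(traj2$x[pres2] >= 0 & traj2$x[pres2] <= 1280))
  expect_true(all(traj2$y[pres2] >= 0 & traj2$y[pres2] <= 768))

  seg <- trajectory_segments(traj2)
  expect_true(all(traj2$x[seg$start_row] == p2$shelter_anchor[1]))

  bad <- simulation_params(duration = 10, border_margin = 200,
                           shelter_anchor = c(50, 50), seed = 1)
  expect_error(simulate_path(simulate_occupancy(bad), bad),
               "outside the inset arena")
})

test_that("uncorrelated walk has mean step length sigma * sqrt(2/pi)", {
  sigma <- 10
  p <- all_visible_params(duration = 100000, seed = 12, step_sigma = sigma,
                          persistence = 0)
  traj <- simulate_path(simulate_occupancy(p), p)
  steps <- diff(complex(real = traj$x, imaginary = traj$y))
  lens <- Mod(steps)
  expected <- sigma * sqrt(2 / pi)
  # half-normal SD of step length, reflection at borders is rare here
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 4 * se)
})

test_that("detector scores follow their Beta laws", {
  p <- all_visible_params(duration = 20000, seed = 21)
  occ <- simulate_occupancy(p)
  traj <- simulate_path(occ, p)
  noise <- noise_params(present_prob = c(8, 2), seed = 31)
  det <- emulate_detections(traj, occ, noise, arena = p$arena)
  target <- pbeta(0.5, 8, 2)
  frac <- mean(det$probability < 0.5)
  se <- sqrt(target * (1 - target) / nrow(det))
  expect_lt(abs(frac - target), 3 * se)
})

test_that("centroid jitter has Rayleigh mean sigma * sqrt(pi/2)", {
  sigma <- 8
  p <- all_visible_params(duration = 20000, seed = 22)
  occ <- simulate_occupancy(p)
  traj <- simulate_path(occ, p)
  noise <- noise_params(jitter_sigma = sigma, outlier_prob = 0, seed = 23)
  det <- emulate_detections(traj, occ, noise, arena = p$arena)
  cen <- bbox_centroid(det)
  err <- sqrt((cen$x - traj$x)^2 + (cen$y - traj$y)^2)
  expected <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt((4 - pi) / 2) / sqrt(length(err))
  expect_lt(abs(mean(err) - expected), 3 * se)
})

test_that("noiseless detections reproduce occupancy and truth exactly", {
  p <- simulation_params(duration = 1000, seed = 33)
  v <- simulate_video(p, noiseless_noise(), video_id = "nz")
  for (tau in c(0.25, 0.5, 0.9)) {
    expect_identical(threshold_series(v$detections$probability, tau),
                     v$occupancy$present)
  }
  cen <- bbox_centroid(v$detections)
  pres <- v$occupancy$present == 1L
  expect_equal(cen$x[pres], v$truth$x[pres])
  expect_equal(cen$y[pres], v$truth$y[pres])
})

test_that("identical params and seed give bit-identical videos", {
  p <- simulation_params(duration = 400, seed = 77)
  n <- noise_params(seed = 78)
  v1 <- simulate_video(p, n, video_id = "d")
  v2 <- simulate_video(p, n, video_id = "d")
  expect_identical(v1$detections, v2$detections)
  expect_identical(v1$truth, v2$truth)

  # different seeds give different draws
  p2 <- p; p2$seed <- 79L
  v3 <- simulate_video(p2, n, video_id = "d")
  expect_false(identical(v1$occupancy$present, v3$occupancy$present))
})

test_that("hidden-frame boxes can land on the novel object", {
  arena <- arena_geometry(object_centroid = c(900, 400))
  p <- simulation_params(duration = 500, p_exit = 0, start_state = "hidden",
                         arena = arena, seed = 41)
  occ <- simulate_occupancy(p)
  traj <- simulate_path(occ, p)
  noise <- noise_params(outlier_box_source = "object_location", seed = 42)
  det <- emulate_detections(traj, occ, noise, arena = arena)
  cen <- bbox_centroid(det)
  expect_true(all(cen$x == 900 & cen$y == 400))
})
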