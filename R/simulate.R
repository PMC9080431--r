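# Synthetic arena: ground-truth shelter occupancy, fish movement and noisy
# detector output with known parameters. Every downstream stage of the
# pipeline is validated by recovering these parameters.
#
# RNG discipline: each simulation stage (occupancy, path, detections) draws
# from its own sub-stream, derived deterministically from the base seed, so
# adding or re-running one stage never shifts another stage's draws.

#' Simulation parameters for ground-truth behaviour
#'
#' The fish alternates between hidden (inside the shelter, invisible to the
#' camera) and visible states following a two-state Markov chain, and moves
#' as a correlated random walk while visible. Every visible bout starts at
#' `shelter_anchor`, the point where the fish re-emerges.
#'
#' @param duration Recording length in seconds.
#' @param p_exit Per-step probability of leaving the shelter
#'   (hidden -> visible), in `[0, 1]`.
#' @param p_enter Per-step probability of entering the shelter
#'   (visible -> hidden), in `[0, 1]`.
#' @param step_sigma Scale (pixels) of the per-step displacement; step
#'   lengths are `|N(0, step_sigma)|`.
#' @param persistence Heading correlation between successive steps, in
#'   `[0, 1)`. 0 gives an uncorrelated random walk.
#' @param start_state `"hidden"` or `"visible"`.
#' @param shelter_anchor Point `c(x, y)` where visible bouts start; must lie
#'   inside the arena.
#' @param arena An [arena_geometry()].
#' @param border_margin Pixels of inset from the arena walls within which the
#'   fish centroid is kept (reflection happens at the inset rectangle). The
#'   fish body has spatial extent, so its centroid cannot reach the wall;
#'   the default margin in [simulate_video()] is the emitted box half-extent.
#' @param frame_interval Seconds per frame (default 1).
#' @param seed Integer seed for the simulation streams.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(duration = 3600, p_exit = 0.02, p_enter = 0.02,
                              step_sigma = 20, persistence = 0.7,
                              start_state = c("hidden", "visible"),
                              shelter_anchor = c(100, 100),
                              arena = arena_geometry(),
                              border_margin = 0,
                              frame_interval = 1, seed = 1L) {
  start_state <- match.arg(start_state)
  assert_scalar_number(duration, "duration", lower = 0)
  assert_scalar_number(p_exit, "p_exit", lower = 0, upper = 1)
  assert_scalar_number(p_enter, "p_enter", lower = 0, upper = 1)
  assert_scalar_number(step_sigma, "step_sigma", lower = 0)
  assert_scalar_number(persistence, "persistence", lower = 0,
                       upper = 1 - 1e-12)
  assert_scalar_number(border_margin, "border_margin", lower = 0,
                       upper = min(arena$width, arena$height) / 2)
  shelter_anchor <- as.numeric(shelter_anchor)
  if (length(shelter_anchor) != 2L ||
      shelter_anchor[1] < 0 || shelter_anchor[1] > arena$width ||
      shelter_anchor[2] < 0 || shelter_anchor[2] > arena$height) {
    stop("`shelter_anchor` must be a point inside the arena", call. = FALSE)
  }
  structure(
    list(duration = duration, p_exit = p_exit, p_enter = p_enter,
         step_sigma = step_sigma, persistence = persistence,
         start_state = start_state, shelter_anchor = shelter_anchor,
         arena = arena, border_margin = border_margin,
         frame_interval = frame_interval, seed = as.integer(seed)),
    class = "simulation_params")
}

#' Detector noise parameters
#'
#' Models the detector's two error channels. The classification probability
#' is drawn from a Beta law conditioned on the true state — `present_prob`
#' when the fish is visible, `absent_prob` when hidden — which makes
#' threshold-dependent miss and false-positive rates analytically available
#' through the Beta CDF. The emitted box centroid is the true position plus
#' per-axis Gaussian jitter, except that with probability `outlier_prob`
#' (and on every hidden frame) the box is relocated: either uniformly in the
#' arena or onto the novel object, reproducing the detector's occasional
#' confusion of the object for a fish and the resulting small-mean /
#' large-SD error structure.
#'
#' @param present_prob,absent_prob Either a length-2 vector `c(shape1,
#'   shape2)` of Beta parameters, or a single value in `[0, 1]` for a
#'   degenerate point mass (used for exact noiseless tests).
#' @param jitter_sigma Per-axis Gaussian centroid noise, pixels.
#' @param outlier_prob Probability that a visible frame's box is relocated.
#' @param outlier_box_source `"random_location"` (uniform over the arena
#'   inset by the box half-extent) or `"object_location"` (at the arena's
#'   novel-object centroid).
#' @param box_halfwidth,box_halfheight Half-extent (pixels) of emitted
#'   boxes.
#' @param seed Integer seed for the detection stream; when `NULL`,
#'   [simulate_video()] derives one from the simulation seed.
#'
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(present_prob = c(8, 2), absent_prob = c(2, 8),
                         jitter_sigma = 5, outlier_prob = 0.01,
                         outlier_box_source = c("random_location",
                                                "object_location"),
                         box_halfwidth = 40, box_halfheight = 25,
                         seed = NULL) {
  outlier_box_source <- match.arg(outlier_box_source)
  check_dist <- function(d, name) {
    d <- as.numeric(d)
    if (length(d) == 1L) {
      assert_scalar_number(d, name, lower = 0, upper = 1)
    } else if (length(d) == 2L) {
      if (any(d <= 0)) stop(sprintf("`%s` Beta shapes must be > 0", name),
                            call. = FALSE)
    } else {
      stop(sprintf("`%s` must be Beta shapes c(a, b) or a point mass", name),
           call. = FALSE)
    }
    d
  }
  assert_scalar_number(jitter_sigma, "jitter_sigma", lower = 0)
  assert_scalar_number(outlier_prob, "outlier_prob", lower = 0, upper = 1)
  assert_scalar_number(box_halfwidth, "box_halfwidth", lower = 0)
  assert_scalar_number(box_halfheight, "box_halfheight", lower = 0)
  structure(
    list(present_prob = check_dist(present_prob, "present_prob"),
         absent_prob = check_dist(absent_prob, "absent_prob"),
         jitter_sigma = jitter_sigma, outlier_prob = outlier_prob,
         outlier_box_source = outlier_box_source,
         box_halfwidth = box_halfwidth, box_halfheight = box_halfheight,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "noise_params")
}

draw_score <- function(n, dist) {
  if (length(dist) == 1L) rep(dist, n) else stats::rbeta(n, dist[1], dist[2])
}

#' CDF of a detector score law
#'
#' `P(score <= q)` under the Beta (or point-mass) law of [noise_params()];
#' used to compute the expected miss and false-positive rates at a
#' threshold.
#'
#' @param q Quantile.
#' @param dist Length-2 Beta shapes or a single point-mass value.
#' @return The CDF value.
#' @export
score_cdf <- function(q, dist) {
  if (length(dist) == 1L) as.numeric(dist <= q) else stats::pbeta(q, dist[1], dist[2])
}

#' Simulate shelter occupancy
#'
#' Two-state Markov chain over hidden/visible at one state per frame. The
#' stationary visible fraction is `p_exit / (p_exit + p_enter)` and mean
#' bout lengths are `1/p_enter` (visible) and `1/p_exit` (hidden).
#'
#' @param params A [simulation_params()].
#' @param video_id Video label for the returned series.
#' @return An [annotation_series()] of length `duration / frame_interval`.
#' @export
simulate_occupancy <- function(params, video_id = "sim") {
  stopifnot(inherits(params, "simulation_params"))
  n <- floor(params$duration / params$frame_interval)
  state <- integer(n)
  if (n > 0L) {
    local_seed(derive_seed(params$seed, "occupancy"), {
      u <- stats::runif(n)
      s <- if (params$start_state == "visible") 1L else 0L
      for (t in seq_len(n)) {
        state[t] <- s
        s <- if (s == 1L) {
          if (u[t] < params$p_enter) 0L else 1L
        } else {
          if (u[t] < params$p_exit) 1L else 0L
        }
      }
    })
  }
  annotation_series(seq_len(n) - 1L, state, video_id = video_id,
                    frame_interval = params$frame_interval)
}

#' Simulate the fish's true path
#'
#' Correlated random walk over the visible frames of an occupancy series:
#' the heading at each step is a persistence-weighted blend of the previous
#' heading and a fresh uniformly random direction, the step length is
#' `|N(0, step_sigma)|`, and positions are folded back into the (inset)
#' arena by reflection at the borders. Each visible bout restarts at
#' `shelter_anchor`; hidden frames carry no position. Positions are
#' quantised to a 1/16-pixel lattice — finer than any detector delivers —
#' which keeps box arithmetic on the true path exact in floating point.
#'
#' @param occupancy An [annotation_series()] of true presence.
#' @param params A [simulation_params()].
#' @return A [trajectory()] with the true centroid per visible frame.
#' @export
simulate_path <- function(occupancy, params) {
  stopifnot(inherits(params, "simulation_params"))
  validate_annotation_series(occupancy)
  arena <- params$arena
  m <- params$border_margin
  lo_x <- m; hi_x <- arena$width - m
  lo_y <- m; hi_y <- arena$height - m
  anchor <- params$shelter_anchor
  if (anchor[1] < lo_x || anchor[1] > hi_x ||
      anchor[2] < lo_y || anchor[2] > hi_y) {
    stop("`shelter_anchor` lies outside the inset arena", call. = FALSE)
  }
  n <- nrow(occupancy)
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  visible <- occupancy$present == 1L
  if (any(visible)) {
    local_seed(derive_seed(params$seed, "path"), {
      heading <- stats::runif(1, 0, 2 * pi)
      prev <- anchor
      in_bout <- FALSE
      for (t in seq_len(n)) {
        if (!visible[t]) {
          in_bout <- FALSE
          next
        }
        if (!in_bout) {
          # re-emergence: bout starts at the shelter anchor
          prev <- anchor
          heading <- stats::runif(1, 0, 2 * pi)
          x[t] <- anchor[1]; y[t] <- anchor[2]
          in_bout <- TRUE
          next
        }
        fresh <- stats::runif(1, 0, 2 * pi)
        hx <- params$persistence * cos(heading) +
          (1 - params$persistence) * cos(fresh)
        hy <- params$persistence * sin(heading) +
          (1 - params$persistence) * sin(fresh)
        nrm <- sqrt(hx^2 + hy^2)
        if (nrm < 1e-12) {          # opposing directions cancelled out
          heading <- fresh
        } else {
          heading <- atan2(hy, hx)
        }
        len <- abs(stats::rnorm(1, 0, params$step_sigma))
        px <- reflect_into(prev[1] + len * cos(heading), lo_x, hi_x)
        py <- reflect_into(prev[2] + len * sin(heading), lo_y, hi_y)
        px <- round(px * 16) / 16    # sub-pixel lattice, exact in doubles
        py <- round(py * 16) / 16
        x[t] <- px; y[t] <- py
        prev <- c(px, py)
      }
    })
  }
  trajectory(occupancy$frame_index, visible, x, y,
             video_id = video_id(occupancy),
             frame_interval = params$frame_interval)
}

#' Emulate noisy detector output
#'
#' Produces one detection record per frame. The classification probability
#' is drawn from the present-law on visible frames and the absent-law on
#' hidden frames. On visible frames the emitted box is centred at the true
#' position plus per-axis Gaussian jitter, except with probability
#' `outlier_prob` the box is relocated to the outlier source; hidden-frame
#' boxes always come from the outlier source (the detector latches onto
#' something else in the empty arena). Boxes are clipped to the arena.
#'
#' @param truth A [trajectory()] with the true positions.
#' @param occupancy The matching [annotation_series()].
#' @param noise A [noise_params()]; its `seed` must be set (or use
#'   [simulate_video()], which derives one).
#' @param arena An [arena_geometry()].
#' @return A [detection_series()].
#' @export
emulate_detections <- function(truth, occupancy, noise,
                               arena = arena_geometry()) {
  stopifnot(inherits(noise, "noise_params"))
  validate_annotation_series(occupancy)
  stopifnot(inherits(truth, "trajectory"))
  if (nrow(truth) != nrow(occupancy) ||
      !all(truth$frame_index == occupancy$frame_index)) {
    stop("truth and occupancy cover different frames", call. = FALSE)
  }
  if (is.null(noise$seed)) {
    stop("`noise$seed` is not set; give noise_params() a seed or use ",
         "simulate_video()", call. = FALSE)
  }
  n <- nrow(occupancy)
  visible <- occupancy$present == 1L
  hw <- noise$box_halfwidth
  hh <- noise$box_halfheight
  prob <- numeric(n)
  cx <- numeric(n)
  cy <- numeric(n)
  local_seed(derive_seed(noise$seed, "detections"), {
    prob[visible] <- draw_score(sum(visible), noise$present_prob)
    prob[!visible] <- draw_score(sum(!visible), noise$absent_prob)
    outlier <- rep(TRUE, n)
    outlier[visible] <- stats::runif(sum(visible)) < noise$outlier_prob
    n_reg <- sum(visible & !outlier)
    cx[visible & !outlier] <- truth$x[visible & !outlier] +
      stats::rnorm(n_reg, 0, noise$jitter_sigma)
    cy[visible & !outlier] <- truth$y[visible & !outlier] +
      stats::rnorm(n_reg, 0, noise$jitter_sigma)
    n_out <- sum(outlier)
    if (n_out > 0L) {
      if (noise$outlier_box_source == "object_location") {
        oc <- arena$object_centroid
        if (is.null(oc)) {
          stop("outlier_box_source = 'object_location' needs an arena ",
               "object_centroid", call. = FALSE)
        }
        cx[outlier] <- oc[1]
        cy[outlier] <- oc[2]
      } else {
        cx[outlier] <- stats::runif(n_out, hw, arena$width - hw)
        cy[outlier] <- stats::runif(n_out, hh, arena$height - hh)
      }
    }
  })
  # clamp centroids into the frame (extreme jitter near a wall), then clip
  # the box corners to the arena
  cx <- pmin(pmax(cx, 0), arena$width)
  cy <- pmin(pmax(cy, 0), arena$height)
  box <- data.frame(
    x_min = pmax(cx - hw, 0), y_min = pmax(cy - hh, 0),
    x_max = pmin(cx + hw, arena$width), y_max = pmin(cy + hh, arena$height))
  detection_series(occupancy$frame_index, prob, box,
                   video_id = video_id(occupancy),
                   frame_interval = frame_interval(occupancy))
}

#' Simulate one complete synthetic video
#'
#' Chains [simulate_occupancy()], [simulate_path()] and
#' [emulate_detections()] into the full record for one synthetic video:
#' the ground-truth occupancy and path, and the noisy detector output.
#' Unless overridden, the path's border margin is the emitted box
#' half-extent plus four jitter standard deviations: the fish body (and its
#' jittered box) then stays wholly inside the frame, clipping is a rare
#' pathology rather than a systematic truncation of the noise, and in the
#' noiseless limit detector centroids reproduce the truth exactly.
#'
#' @param params A [simulation_params()].
#' @param noise A [noise_params()]; a missing `seed` is derived from
#'   `params$seed`.
#' @param video_id Video label.
#' @param test_type `"ACT"` (open-field activity) or `"EXP"`
#'   (novel-object exploration).
#' @return A list with elements `video_id`, `test_type`, `params`, `noise`,
#'   `occupancy` (annotation series), `truth` (trajectory) and `detections`
#'   (detection series), of class `synthetic_video`.
#' @export
simulate_video <- function(params = simulation_params(),
                           noise = noise_params(),
                           video_id = "sim", test_type = c("ACT", "EXP")) {
  test_type <- match.arg(test_type)
  stopifnot(inherits(params, "simulation_params"),
            inherits(noise, "noise_params"))
  if (params$border_margin == 0) {
    params$border_margin <- max(noise$box_halfwidth, noise$box_halfheight) +
      4 * noise$jitter_sigma
  }
  if (is.null(noise$seed)) {
    noise$seed <- derive_seed(params$seed, "noise")
  }
  occupancy <- simulate_occupancy(params, video_id = video_id)
  truth <- simulate_path(occupancy, params)
  detections <- emulate_detections(truth, occupancy, noise,
                                   arena = params$arena)
  structure(
    list(video_id = video_id, test_type = test_type, params = params,
         noise = noise, occupancy = occupancy, truth = truth,
         detections = detections),
    class = "synthetic_video")
}

#' Boxes centred on the true path
#'
#' The manual-annotation stand-in for synthetic videos: a box of the
#' emitted half-extent centred on each visible frame's true position.
#'
#' @param video A `synthetic_video` from [simulate_video()].
#' @return A data frame of boxes with `video_id` and `frame_index` columns.
#' @export
truth_boxes <- function(video) {
  stopifnot(inherits(video, "synthetic_video"))
  truth <- video$truth
  vis <- truth$present
  hw <- video$noise$box_halfwidth
  hh <- video$noise$box_halfheight
  arena <- video$params$arena
  data.frame(video_id = video$video_id,
             frame_index = truth$frame_index[vis],
             x_min = pmax(truth$x[vis] - hw, 0),
             y_min = pmax(truth$y[vis] - hh, 0),
             x_max = pmin(truth$x[vis] + hw, arena$width),
             y_max = pmin(truth$y[vis] + hh, arena$height))
}
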