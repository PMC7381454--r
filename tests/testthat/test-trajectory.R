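test_that("spatiotemporal cropping selects the window and the ROI", {
  frames <- lapply(1:200, function(i) array(i / 200, dim = c(40, 60, 3)))
  meta <- trial_video_meta(roi_px = c(10, 5, 20, 15), start_frame = 51,
                          end_frame = 150)
  out <- crop_spatiotemporal(frames, meta)
  expect_length(out, 100)
  expect_identical(dim(out[[1]]), c(15L, 20L, 3L))
  expect_equal(out[[1]][1, 1, 1], 51 / 200)

  # full-frame no-op crop
  meta2 <- trial_video_meta(start_frame = 1, end_frame = 200)
  expect_identical(crop_spatiotemporal(frames, meta2), frames)

  expect_error(trial_video_meta(start_frame = 100, end_frame = 50),
               "must not exceed")
  meta3 <- trial_video_meta(start_frame = 1, end_frame = 10,
                            roi_px = c(50, 30, 20, 20))
  expect_error(crop_spatiotemporal(frames, meta3), "ROI")
})

test_that("frames_per_beat computes the metronome-frame ratio", {
  expect_equal(frames_per_beat(50, 70), 50 * 60 / 70)
  expect_equal(frames_per_beat(50, 50), 60)
  expect_equal(frames_per_beat(25, 70), 25 * 60 / 70)
  expect_error(frames_per_beat(0, 70), "positive")
  expect_error(frames_per_beat(50, -1), "positive")
})

test_that("beat sampling picks the nearest frames and the right count", {
  mk_obs <- function(n) data.frame(frame = 1:n, x_px = as.numeric(1:n),
                                   y_px = 0, status = "detected")
  # 300 frames at the study settings: floor(299 / 42.857) + 1 = 7 beats
  b <- sample_beats(mk_obs(300), trial_video_meta(fps = 50, bpm = 70))
  expect_identical(nrow(b), 7L)
  # integer spacing: 121 frames at fps 50 / bpm 50 -> frames 1, 61, 121
  b <- sample_beats(mk_obs(121), trial_video_meta(fps = 50, bpm = 50))
  expect_identical(b$frame, c(1L, 61L, 121L))
  # minimal case
  b <- sample_beats(mk_obs(1), trial_video_meta())
  expect_identical(nrow(b), 1L)
  expect_error(sample_beats(data.frame(frame = integer(0), x_px = numeric(0),
                                       y_px = numeric(0), status = character(0))),
               "no observations")
})

test_that("snapping recovers cells exactly at centers and under small jitter", {
  g <- small_grid()
  det <- small_detection()
  cal <- det$calibration
  cells <- c(5L, 17L, 30L, 44L, 60L)
  ctr_px <- cm_to_px(cal, as.matrix(g$cells[cells, c("x_cm", "y_cm")]))
  bp <- data.frame(beat = seq_along(cells), frame = seq_along(cells),
                   x_px = ctr_px[, 1], y_px = ctr_px[, 2], status = "detected")
  tr <- form_trajectory(bp, det)
  expect_identical(tr$cell, cells)
  expect_equal(tr$x_cm, g$cells$x_cm[cells], tolerance = 1e-6)

  # jitter below half the minimum center spacing keeps the same cells
  set.seed(5)
  half <- 0.5 * sqrt(3) * g$spec$cell_size * det$px_per_cm
  bp2 <- bp
  ang <- runif(nrow(bp), 0, 2 * pi); rad <- runif(nrow(bp), 0, 0.9 * half)
  bp2$x_px <- bp$x_px + rad * cos(ang)
  bp2$y_px <- bp$y_px + rad * sin(ang)
  expect_identical(form_trajectory(bp2, det)$cell, cells)

  # out-of-board positions are clamped to the nearest cell and flagged
  bp3 <- bp[1, ]; bp3$x_px <- -30; bp3$y_px <- -30
  tr3 <- form_trajectory(bp3, det)
  expect_true(tr3$out_of_board[1])
  expect_true(tr3$cell[1] %in% seq_len(nrow(g$cells)))
})

test_that("the distance series matches closed forms and brute force", {
  g <- small_grid()
  mk_traj <- function(cells) {
    structure(data.frame(beat = seq_along(cells), frame = seq_along(cells),
                         agent = "x", x_px = NA_real_, y_px = NA_real_,
                         q = g$cells$q[cells], r = g$cells$r[cells],
                         x_cm = g$cells$x_cm[cells], y_cm = g$cells$y_cm[cells],
                         cell = cells, status = "detected",
                         out_of_board = FALSE),
              class = c("trajectory", "data.frame"))
  }
  a <- mk_traj(c(10L, 11L, 12L))
  expect_equal(distance_series(a, a)$distances_cm, rep(0, 3))
  expect_equal(distance_series(a, a)$mean_distance, 0)

  # agents two columns apart in the same row: distance = 2 * (3/4 * w)
  i <- which(g$cells$q == 2 & g$cells$r == 1)
  j <- which(g$cells$q == 4 & g$cells$r == 1)
  d <- distance_series(mk_traj(rep(i, 4)), mk_traj(rep(j, 4)))
  expect_equal(d$distances_cm, rep(2 * 0.75 * 3, 4))
  expect_equal(d$mean_distance, 4.5)

  # random trajectories against direct summation
  set.seed(9)
  ca <- sample(nrow(g$cells), 25, replace = TRUE)
  cb <- sample(nrow(g$cells), 25, replace = TRUE)
  ds <- distance_series(mk_traj(ca), mk_traj(cb))
  brute <- mean(sqrt((g$cells$x_cm[ca] - g$cells$x_cm[cb])^2 +
                       (g$cells$y_cm[ca] - g$cells$y_cm[cb])^2))
  expect_equal(ds$mean_distance, brute)

  # symmetry
  expect_equal(distance_series(mk_traj(cb), mk_traj(ca))$mean_distance, brute)

  # unequal lengths truncate with a warning
  expect_warning(dt <- distance_series(mk_traj(ca), mk_traj(cb[1:10])),
                 "truncating")
  expect_length(dt$distances_cm, 10)
})

test_that("escape detection looks at every beat and the right edge", {
  g <- small_grid()
  spec <- small_spec()
  rightmost <- which.max(g$cells$x_cm)
  leftmost <- which.min(g$cells$x_cm)
  mk <- function(cells) data.frame(x_cm = g$cells$x_cm[cells],
                                   y_cm = g$cells$y_cm[cells])
  expect_true(escape_reached(mk(c(leftmost, rightmost)), spec))
  expect_false(escape_reached(mk(rep(leftmost, 5))[
    , , drop = FALSE], spec))
  # touching the right edge mid-trial counts
  expect_true(escape_reached(mk(c(leftmost, rightmost, leftmost)), spec))
})
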