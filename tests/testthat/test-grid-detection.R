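test_that("grid centers are recovered from a noiseless rendered board", {
  g <- small_grid()
  cfg <- noiseless_config()
  det <- small_detection()
  cal <- hexpursuit:::board_calibration(g, cfg)
  true_px <- cm_to_px(cal, as.matrix(g$cells[, c("x_cm", "y_cm")]))
  err <- sqrt(rowSums((det$centers_px - true_px)^2))
  w_px <- 2 * g$spec$cell_size * cfg$px_per_cm
  expect_gte(mean(err <= 0.25 * w_px), 0.99)
  expect_equal(nrow(det$centers_px), nrow(det$matched_grid$cells))
  expect_gt(det$px_per_cm, 0)
  # every center inside the image
  expect_true(all(det$centers_px[, 1] >= 0 &
                    det$centers_px[, 1] < cfg$image_size_px[1]))
  expect_true(all(det$centers_px[, 2] >= 0 &
                    det$centers_px[, 2] < cfg$image_size_px[2]))
})

test_that("erased cells are restored by the repair path and flagged", {
  g <- small_grid()
  cfg <- noiseless_config()
  img <- render_board(g, cfg)
  cal <- hexpursuit:::board_calibration(g, cfg)
  # erase the line segments of 5 interior cells by painting board gray over
  # a disk covering each hexagon and its edges
  interior <- which(lengths(g$neighbors) == 6)
  erased <- interior[seq(1, length(interior), length.out = 5)]
  for (i in erased) {
    ctr <- cm_to_px(cal, c(g$cells$x_cm[i], g$cells$y_cm[i]))
    img <- hexpursuit:::draw_disk(img, ctr[1, ],
                                  g$spec$cell_size * cfg$px_per_cm * 1.05,
                                  rep(cfg$board_gray, 3))
  }
  det <- detect_grid_centers(img, small_spec())
  expect_true(all(det$repaired_flags[erased]))
  true_px <- cm_to_px(cal, as.matrix(g$cells[erased, c("x_cm", "y_cm")]))
  err <- sqrt(rowSums((det$centers_px[erased, , drop = FALSE] - true_px)^2))
  w_px <- 2 * g$spec$cell_size * cfg$px_per_cm
  expect_true(all(err <= 0.25 * w_px))
})

test_that("a blank image fails detection with a diagnostic error", {
  blank <- array(1, dim = c(120, 160, 3))
  expect_error(detect_grid_centers(blank, small_spec()), "detection failed")
})

test_that("validate_and_repair is identity on a clean lattice and repairs displacements", {
  g <- small_grid()
  s <- 10 * sqrt(3) * g$spec$cell_size  # lattice at 10 px/cm, y down
  pts <- cbind(10 * g$cells$x_cm, -10 * g$cells$y_cm + 400)
  vr <- validate_and_repair(pts, s)
  expect_identical(vr$centers_px, pts)
  expect_false(any(vr$repaired_flags))

  # displace one interior point by 0.6 spacing
  i <- which(lengths(g$neighbors) == 6)[3]
  bad <- pts
  bad[i, ] <- bad[i, ] + c(0.6 * s, 0)
  vr <- validate_and_repair(bad, s)
  expect_true(vr$repaired_flags[i])
  expect_false(any(vr$repaired_flags[-i]))
  expect_lt(sqrt(sum((vr$centers_px[i, ] - pts[i, ])^2)), 0.01 * s)
  # unflagged points never move
  expect_identical(vr$centers_px[-i, ], bad[-i, ])

  # jitter below half the tolerance: all accepted
  set.seed(7)
  tol <- grid_detector_config()$corner_distance_tolerance
  ang <- runif(nrow(pts), 0, 2 * pi)
  rad <- runif(nrow(pts), 0, tol / 2 * s)
  jit <- pts + cbind(rad * cos(ang), rad * sin(ang))
  vr <- validate_and_repair(jit, s)
  expect_false(any(vr$repaired_flags))

  expect_error(validate_and_repair(pts[1:4, ] + 0.4 * s * matrix(rnorm(8), 4), s),
               "fewer than 3 consistent")
})

test_that("calibration recovers the renderer scale", {
  g <- small_grid()
  for (ppc in c(10, 5)) {
    cfg <- noiseless_config(px_per_cm = ppc)
    det <- detect_grid_centers(render_board(g, cfg), small_spec())
    expect_lt(abs(det$px_per_cm - ppc), 0.01 * ppc)
    # calibrate() against the known cm centers agrees
    s <- calibrate(det$centers_px, as.matrix(g$cells[, c("x_cm", "y_cm")]))
    expect_lt(abs(s - ppc), 0.01 * ppc)
  }
  expect_error(calibrate(matrix(1, 1, 2), matrix(1, 1, 2)), "at least 2")
  expect_error(calibrate(matrix(1, 3, 2), matrix(1, 3, 2)), "coincident")
})

test_that("detection is translation-equivariant", {
  g <- small_grid()
  cfg <- noiseless_config()
  img <- render_board(g, cfg)
  det1 <- detect_grid_centers(img, small_spec())
  dx <- 7L; dy <- 4L
  shifted <- array(1, dim = dim(img))
  shifted[(dy + 1):dim(img)[1], (dx + 1):dim(img)[2], ] <-
    img[1:(dim(img)[1] - dy), 1:(dim(img)[2] - dx), ]
  det2 <- detect_grid_centers(shifted, small_spec())
  delta <- det2$centers_px - det1$centers_px
  expect_true(all(abs(delta[, 1] - dx) < 0.5))
  expect_true(all(abs(delta[, 2] - dy) < 0.5))
})

test_that("localization stays accurate across seeds and illumination gradients", {
  g <- small_grid()
  errs <- numeric(20)
  for (k in 1:20) {
    grad <- ((k %% 5) - 2) / 10  # gradients in {-0.2, ..., +0.2}
    cfg <- small_render_config(illumination_gradient = grad, seed = k)
    det <- detect_grid_centers(render_board(g, cfg), small_spec())
    cal <- hexpursuit:::board_calibration(g, cfg)
    true_px <- cm_to_px(cal, as.matrix(g$cells[, c("x_cm", "y_cm")]))
    errs[k] <- mean(sqrt(rowSums((det$centers_px - true_px)^2)))
  }
  w_px <- 2 * g$spec$cell_size * 8
  expect_lt(mean(errs), 0.1 * w_px)
})
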