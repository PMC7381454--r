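test_that("the prey's red blob is localized by the Hough transform", {
  obs <- detect_prey(plain_frame(prey = c(80, 60)))
  expect_identical(obs$status, "detected")
  expect_lt(sqrt(sum((obs$center_px - c(80, 60))^2)), 2)

  # no red pixels at all
  obs <- detect_prey(plain_frame())
  expect_identical(obs$status, "missing")

  # single-pixel red speckles are removed by the median filter
  f <- plain_frame(prey = c(40, 90))
  set.seed(11)
  for (k in 1:20) {
    f[sample(120, 1), sample(160, 1), ] <- c(1, 0.2, 0.2)
  }
  obs <- detect_prey(f)
  expect_identical(obs$status, "detected")
  expect_lt(sqrt(sum((obs$center_px - c(40, 90))^2)), 2)

  expect_error(detect_prey(matrix(0.5, 50, 50)), "3-channel")
})

test_that("the predator's black dot is found after component filtering and closing", {
  obs <- detect_predator(plain_frame(predator = c(100, 40)))
  expect_identical(obs$status, "detected")
  expect_lt(sqrt(sum((obs$center_px - c(100, 40))^2)), 2)

  # components of 5 and 9 px only: both below the ten-pixel threshold
  m <- mask_with_components(c(5, 9))
  f <- array(245 / 255, dim = c(nrow(m), ncol(m), 3))
  for (ch in 1:3) f[, , ch][m == 1] <- 20 / 255
  obs <- detect_predator(f)
  expect_identical(obs$status, "missing")

  # 9 px and 10 px: exactly the 10-px component is detected
  m <- mask_with_components(c(9, 10))
  truth10 <- which(m == 1, arr.ind = TRUE)
  f <- array(245 / 255, dim = c(nrow(m), ncol(m), 3))
  for (ch in 1:3) f[, , ch][m == 1] <- 20 / 255
  obs <- detect_predator(f)
  expect_identical(obs$status, "detected")
  # the surviving component is the second (10-px) one, far from the first
  lab <- EBImage::bwlabel(m)
  sz <- tabulate(lab[lab > 0])
  comp10 <- which(lab == which(sz == 10), arr.ind = TRUE)
  c10 <- c(mean(comp10[, 2]), mean(comp10[, 1])) - 1
  expect_lt(sqrt(sum((obs$center_px - c10)^2)), 4)
})

test_that("remove_small_components keeps exactly the >= min_px components", {
  empty <- matrix(0L, 20, 20)
  expect_identical(remove_small_components(empty, 10), empty)

  m <- mask_with_components(c(5, 9, 10, 25))
  out <- remove_small_components(m, 10)
  # oracle: independent flood-fill labeling
  expect_identical(sort(flood_component_sizes(out)), c(10L, 25L))
  expect_identical(sum(flood_component_sizes(m) >= 10), 2L)

  # min_px = 1 is a no-op
  expect_identical(remove_small_components(m, 1), m)

  # idempotence
  expect_identical(remove_small_components(out, 10), out)
})

test_that("morphological close never shrinks a surviving component", {
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(0L, 60, 60)
    ctr <- c(sample(15:45, 1), sample(15:45, 1))
    r <- sample(3:6, 1)
    for (i in 1:60) for (j in 1:60) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) m[i, j] <- 1L
    }
    closed <- EBImage::closing(m, EBImage::makeBrush(5, "disc"))
    expect_gte(sum(closed), sum(m))
  }
})

test_that("track_trial yields one observation per agent per frame with hold-last fill", {
  frames <- lapply(1:12, function(i) {
    plain_frame(prey = c(20 + 4 * i, 60), predator = c(20 + 4 * i, 30))
  })
  # occlude the prey in frames 6:8
  for (i in 6:8) frames[[i]] <- plain_frame(predator = c(20 + 4 * i, 30))
  obs <- track_trial(frames)
  expect_identical(nrow(obs), 24L)
  op <- obs[obs$agent == "prey", ]
  expect_identical(op$status[6:8], rep("missing", 3))
  expect_equal(op$x_px[6:8], rep(op$x_px[5], 3))
  expect_true(all(op$status[-(6:8)] == "detected"))
  err <- abs(op$x_px[-(6:8)] - (20 + 4 * (1:12))[-(6:8)])
  expect_lt(mean(err), 2)

  # one-frame sequence
  obs1 <- track_trial(frames[1])
  expect_identical(nrow(obs1), 2L)
  expect_error(track_trial(list()), "empty")
})

test_that("detected centers always lie inside the frame", {
  set.seed(21)
  for (k in 1:10) {
    f <- plain_frame(prey = c(runif(1, 5, 155), runif(1, 5, 115)),
                     predator = c(runif(1, 5, 155), runif(1, 5, 115)))
    for (o in list(detect_prey(f), detect_predator(f))) {
      if (o$status == "detected") {
        expect_true(o$center_px[1] >= 0 && o$center_px[1] < 160 &&
                      o$center_px[2] >= 0 && o$center_px[2] < 120)
      }
    }
  }
})
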