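# Shared fixtures, built once per test run. A small 30 x 20 cm board keeps
# the vision tests fast while exercising every pipeline stage.

fixture_env <- new.env()

small_spec <- function() hex_grid_spec(cell_size = 1.5, board_width = 30,
                                       board_height = 20)

small_grid <- function() {
  if (is.null(fixture_env$grid)) fixture_env$grid <- hex_grid(small_spec())
  fixture_env$grid
}

small_render_config <- function(...) {
  render_config(px_per_cm = 8, image_size_px = c(320L, 220L), ...)
}

noiseless_config <- function(px_per_cm = 8, ...) {
  render_config(px_per_cm = px_per_cm, image_size_px = c(320L, 220L),
                illumination_gradient = 0, speckle_count = 0L, ...)
}

# Grid detection on the clean small board, computed once.
small_detection <- function() {
  if (is.null(fixture_env$detection)) {
    img <- render_board(small_grid(), noiseless_config())
    fixture_env$detection <- detect_grid_centers(img, small_spec())
  }
  fixture_env$detection
}

# A plain board-colored frame with optional prey/predator disks at given
# 0-based pixel centers; no hexagon lines, for marker-only tests.
plain_frame <- function(w = 160L, h = 120L, prey = NULL, predator = NULL,
                        prey_r = 6, pred_r = 5) {
  img <- array(245 / 255, dim = c(h, w, 3))
  if (!is.null(prey)) {
    img <- hexpursuit:::draw_disk(img, prey, prey_r, c(230, 30, 30) / 255)
  }
  if (!is.null(predator)) {
    img <- hexpursuit:::draw_disk(img, predator, pred_r, c(20, 20, 20) / 255)
  }
  img
}

# Independent connected-component labeling oracle (8-connectivity), by
# breadth-first flood fill; used to cross-check remove_small_components.
flood_component_sizes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  sizes <- integer(0)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE; sz <- 0L
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]; sz <- sz + 1L
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= h && b >= 1 && b <= w &&
            mask[a, b] != 0 && !seen[a, b]) {
          seen[a, b] <- TRUE
          queue[[length(queue) + 1L]] <- c(a, b)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# Binary mask with 8-connected components of exactly the requested pixel
# counts, spaced well apart.
mask_with_components <- function(sizes, w = 120L, h = 80L) {
  m <- matrix(0L, h, w)
  x0 <- 10L
  for (s in sizes) {
    cols <- ceiling(s / 4)
    filled <- 0L
    for (cc in seq_len(cols)) for (rr in 1:4) {
      if (filled < s) { m[10L + rr, x0 + cc] <- 1L; filled <- filled + 1L }
    }
    x0 <- x0 + cols + 10L
  }
  m
}
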