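# Synthetic scene renderer: board images and full trial frame sequences with
# per-frame ground truth. Images are numeric arrays in [0, 1], indexed
# [row (y, down), col (x, right)] with a third dimension for RGB color.
# Continuous pixel coordinates are 0-based: pixel (i, j) has center (x = j, y = i).

#' Renderer configuration
#'
#' @param px_per_cm Rendering scale (default 10).
#' @param image_size_px Length-2 integer `c(width, height)` of the output
#'   frames (default 1280 x 720, the camera resolution being emulated).
#' @param prey_radius_px Radius of the bright red prey disk (default 6).
#' @param predator_radius_px Radius of the black predator dot (default 5).
#' @param illumination_gradient Fractional intensity slope left to right:
#'   0 is flat lighting, 0.2 shades the image from 80% to 120% intensity.
#'   The default 0.1 emulates the mild lighting nonuniformity of an
#'   ambient-lit room; pass 0 for a noiseless scene.
#' @param speckle_count Number of single-pixel bright red speckles per frame,
#'   emulating stray laser reflections (default 20; 0 for a noiseless scene).
#' @param seed Integer seed controlling speckle placement (default 1).
#' @return An object of class `render_config`.
#' @export
render_config <- function(px_per_cm = 10, image_size_px = c(1280L, 720L),
                          prey_radius_px = 6, predator_radius_px = 5,
                          illumination_gradient = 0.1, speckle_count = 20L,
                          seed = 1L) {
  stopifnot(px_per_cm > 0, length(image_size_px) == 2L,
            prey_radius_px >= 2, predator_radius_px >= 2, speckle_count >= 0)
  structure(list(px_per_cm = px_per_cm,
                 image_size_px = as.integer(image_size_px),
                 prey_radius_px = prey_radius_px,
                 predator_radius_px = predator_radius_px,
                 illumination_gradient = illumination_gradient,
                 speckle_count = as.integer(speckle_count),
                 seed = as.integer(seed),
                 board_gray = 245 / 255, line_gray = 0.55,
                 outside_gray = 0.80,
                 prey_rgb = c(230, 30, 30) / 255,
                 predator_rgb = c(20, 20, 20) / 255),
            class = "render_config")
}

# Affine map between board cm coordinates (origin lower-left, y up) and
# continuous pixel coordinates (origin top-left, y down), for a board
# centered in the image at the configured scale.
board_calibration <- function(grid, config) {
  s <- config$px_per_cm
  bw <- grid$spec$board_width * s
  bh <- grid$spec$board_height * s
  iw <- config$image_size_px[1]; ih <- config$image_size_px[2]
  if (bw > iw || bh > ih) {
    stop(sprintf("board (%g x %g px at %g px/cm) does not fit image (%d x %d)",
                 bw, bh, s, iw, ih), call. = FALSE)
  }
  mx <- (iw - bw) / 2; my <- (ih - bh) / 2
  cal <- list(px_per_cm = s,
              ox = mx - s * grid$spec$origin[1],
              oy = my + bh + s * grid$spec$origin[2])
  class(cal) <- "board_calibration"
  cal
}

#' Convert cm coordinates to pixel coordinates
#' @param cal A calibration list with `px_per_cm`, `ox`, `oy`.
#' @param xy Matrix (or length-2 vector) of points, columns x and y.
#' @return Matrix of pixel coordinates (x right, y down, 0-based).
#' @export
cm_to_px <- function(cal, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L, byrow = TRUE)
  cbind(x = cal$ox + cal$px_per_cm * xy[, 1],
        y = cal$oy - cal$px_per_cm * xy[, 2])
}

#' Convert pixel coordinates to cm coordinates
#' @inheritParams cm_to_px
#' @return Matrix of physical coordinates in cm.
#' @export
px_to_cm <- function(cal, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L, byrow = TRUE)
  cbind(x = (xy[, 1] - cal$ox) / cal$px_per_cm,
        y = (cal$oy - xy[, 2]) / cal$px_per_cm)
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Rasterize a line segment between continuous px points a, b: returns
# cbind(row, col) 1-based pixel indices, clipped to the image.
raster_segment <- function(a, b, dim_hw) {
  len <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(len / 0.4))
  t <- seq(0, 1, length.out = n)
  px <- round(a[1] + t * (b[1] - a[1]))
  py <- round(a[2] + t * (b[2] - a[2]))
  keep <- px >= 0 & px < dim_hw[2] & py >= 0 & py < dim_hw[1]
  cbind(py[keep] + 1L, px[keep] + 1L)
}

# Set a filled disk into an [h, w, 3] array.
draw_disk <- function(img, center_px, radius, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- center_px[1]; y0 <- center_px[2]
  cs <- max(1L, floor(x0 - radius) + 1L):min(w, ceiling(x0 + radius) + 1L)
  rs <- max(1L, floor(y0 - radius) + 1L):min(h, ceiling(y0 + radius) + 1L)
  if (length(cs) == 0L || length(rs) == 0L) return(img)
  dx <- (cs - 1L) - x0; dy <- (rs - 1L) - y0
  inside <- which(outer(dy^2, dx^2, "+") <= radius^2, arr.ind = TRUE)
  if (nrow(inside) == 0L) return(img)
  rr <- rs[inside[, 1]]; cc <- cs[inside[, 2]]
  n <- length(rr)
  img[cbind(rep(rr, 3L), rep(cc, 3L), rep(1:3, each = n))] <-
    rep(rgb, each = n)
  img
}

# Static scene: board rectangle, hexagon outlines, illumination gradient.
render_board_base <- function(grid, config) {
  cal <- board_calibration(grid, config)
  w <- config$image_size_px[1]; h <- config$image_size_px[2]
  img <- array(config$outside_gray, dim = c(h, w, 3))
  corners <- cm_to_px(cal, rbind(
    c(grid$spec$origin[1], grid$spec$origin[2]),
    c(grid$spec$origin[1] + grid$spec$board_width,
      grid$spec$origin[2] + grid$spec$board_height)))
  cs <- (floor(min(corners[, 1])) + 1L):(ceiling(max(corners[, 1])))
  rs <- (floor(min(corners[, 2])) + 1L):(ceiling(max(corners[, 2])))
  img[rs, cs, ] <- config$board_gray

  # hexagon outlines: 6 corners at bearings 0, 60, ..., 300 degrees
  ang <- seq(0, 300, by = 60) * pi / 180
  vx <- grid$spec$cell_size * cos(ang)
  vy <- grid$spec$cell_size * sin(ang)
  pts_list <- vector("list", nrow(grid$cells) * 6L)
  kk <- 0L
  for (i in seq_len(nrow(grid$cells))) {
    vpx <- cm_to_px(cal, cbind(grid$cells$x_cm[i] + vx,
                               grid$cells$y_cm[i] + vy))
    for (e in 1:6) {
      kk <- kk + 1L
      pts_list[[kk]] <- raster_segment(vpx[e, ], vpx[if (e == 6) 1 else e + 1, ],
                                       c(h, w))
    }
  }
  pts <- unique(do.call(rbind, pts_list))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[pts] <- config$line_gray
    img[, , ch] <- plane
  }

  if (config$illumination_gradient != 0) {
    fac <- 1 + config$illumination_gradient *
      (2 * (seq_len(w) - 1) / (w - 1) - 1)
    img <- img * rep(fac, each = h)
    img[img > 1] <- 1; img[img < 0] <- 0
  }
  list(img = img, cal = cal)
}

add_speckles <- function(img, config, frame_seed) {
  if (config$speckle_count <= 0L) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  with_local_seed(frame_seed, {
    rr <- sample.int(h, config$speckle_count, replace = TRUE)
    cc <- sample.int(w, config$speckle_count, replace = TRUE)
  })
  n <- length(rr)
  img[cbind(rep(rr, 3L), rep(cc, 3L), rep(1:3, each = n))] <-
    rep(c(1.0, 0.35, 0.35), each = n)
  img
}

#' Render the empty board
#'
#' White board with dark flat-topped hexagon outlines, centered in the image,
#' with the configured illumination gradient and speckle noise. Deterministic
#' given the config seed.
#'
#' @param grid A [hex_grid()].
#' @param config A [render_config()].
#' @return Numeric array `[height, width, 3]` with values in `[0, 1]`.
#' @export
render_board <- function(grid, config = render_config()) {
  base <- render_board_base(grid, config)
  add_speckles(base$img, config, config$seed)
}

#' Streaming renderer for a full trial
#'
#' Builds the static board once and exposes per-frame rendering as a
#' function, so long trials never hold all frames in memory. Agents move
#' linearly between consecutive beat cell centers; the prey is drawn as a
#' bright red disk and the predator as a near-black dot (drawn last).
#'
#' @param prey_cells,predator_cells Integer vectors of cell row indices into
#'   `grid$cells`, one per beat; equal lengths.
#' @param grid A [hex_grid()].
#' @param config A [render_config()].
#' @param meta A [trial_video_meta()]; its fps and bpm set the number of
#'   frames per beat.
#' @return An object of class `trial_renderer`: list with `n_frames`,
#'   `frame(i)` (1-based; returns the `[h, w, 3]` array for frame `i`),
#'   `truth` (a `trial_ground_truth`), and `calibration`.
#' @export
trial_renderer <- function(prey_cells, predator_cells, grid,
                           config = render_config(), meta = trial_video_meta()) {
  if (length(prey_cells) != length(predator_cells)) {
    stop("prey and predator cell sequences must have equal length", call. = FALSE)
  }
  n_beats <- length(prey_cells)
  if (n_beats < 1L) stop("need at least one beat position", call. = FALSE)
  if (any(prey_cells < 1L | prey_cells > nrow(grid$cells)) ||
      any(predator_cells < 1L | predator_cells > nrow(grid$cells))) {
    stop("cell indices outside the grid", call. = FALSE)
  }
  base <- render_board_base(grid, config)
  cal <- base$cal
  fpb <- frames_per_beat(meta$fps, meta$bpm)
  n_frames <- if (n_beats == 1L) 1L else as.integer(ceiling((n_beats - 1) * fpb)) + 1L

  prey_px <- cm_to_px(cal, cbind(grid$cells$x_cm[prey_cells],
                                 grid$cells$y_cm[prey_cells]))
  pred_px <- cm_to_px(cal, cbind(grid$cells$x_cm[predator_cells],
                                 grid$cells$y_cm[predator_cells]))

  pos_at_frame <- function(path_px, i) {
    if (n_beats == 1L) return(path_px[1L, ])
    t <- (i - 1) / fpb
    k <- min(max(floor(t), 0), n_beats - 2)
    f <- min(max(t - k, 0), 1)
    (1 - f) * path_px[k + 1L, ] + f * path_px[k + 2L, ]
  }

  frames_idx <- seq_len(n_frames)
  truth_xy <- t(vapply(frames_idx, function(i)
    c(pos_at_frame(prey_px, i), pos_at_frame(pred_px, i)), numeric(4)))
  truth <- structure(list(
    frames = data.frame(frame = frames_idx,
                        prey_x = truth_xy[, 1], prey_y = truth_xy[, 2],
                        predator_x = truth_xy[, 3], predator_y = truth_xy[, 4]),
    beats = data.frame(beat = seq_len(n_beats),
                       frame = pmin(round((seq_len(n_beats) - 1) * fpb) + 1, n_frames),
                       prey_cell = prey_cells, predator_cell = predator_cells),
    config = config, grid = grid, meta = meta),
    class = "trial_ground_truth")

  frame_fun <- function(i) {
    stopifnot(i >= 1L, i <= n_frames)
    img <- add_speckles(base$img, config, config$seed + i)
    img <- draw_disk(img, pos_at_frame(prey_px, i), config$prey_radius_px,
                     config$prey_rgb)
    draw_disk(img, pos_at_frame(pred_px, i), config$predator_radius_px,
              config$predator_rgb)
  }

  structure(list(n_frames = n_frames, frame = frame_fun, truth = truth,
                 calibration = cal, grid = grid, config = config, meta = meta),
            class = "trial_renderer")
}

#' Render a full trial into memory
#'
#' Materializes every frame of [trial_renderer()]. Suitable for short trials;
#' for long ones pass the renderer itself to [track_trial()], which streams.
#'
#' @inheritParams trial_renderer
#' @return List with `frames` (list of arrays) and `truth`.
#' @export
render_trial <- function(prey_cells, predator_cells, grid,
                         config = render_config(), meta = trial_video_meta()) {
  tr <- trial_renderer(prey_cells, predator_cells, grid, config, meta)
  list(frames = lapply(seq_len(tr$n_frames), tr$frame), truth = tr$truth,
       calibration = tr$calibration)
}

#' Write a rendered frame to a PNG file
#' @param frame `[h, w, 3]` array in `[0, 1]`.
#' @param path Output file path.
#' @export
write_frame_png <- function(frame, path) {
  EBImage::writeImage(EBImage::Image(aperm(frame, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Read a PNG/JPEG frame as an `[h, w, 3]` array
#' @param path Image file path.
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  aperm(a, c(2, 1, 3))
}
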