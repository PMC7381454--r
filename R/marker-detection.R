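# Per-frame detection of the two markers: the prey (bright red laser point)
# via red-dominance masking, median filtering and a circular Hough transform;
# the predator (black taped magnet) via dark binarization, small-component
# removal, morphological close and a circle fit.

#' Marker detector configuration
#'
#' @param median_kernel Odd window edge for the median filter (default 3,
#'   i.e. 3 x 3).
#' @param min_component_px Connected components with fewer pixels than this
#'   are discarded before the predator circle fit (default 10).
#' @param hough_radius_range_px Length-2 `c(min, max)` circle radii searched
#'   by the Hough transform, in px.
#' @param red_dominance_threshold A pixel is "red" iff
#'   `R - max(G, B) > threshold`, on a 0-255 intensity scale (default 60).
#'   Plain channel separation also fires on the white board, hence the
#'   dominance margin.
#' @param dark_threshold Foreground threshold for the predator binarization
#'   as a fraction of dynamic range (default 0.25): a near-black marker is
#'   far darker than the grey hexagon rule lines.
#' @param binarize_method `"fixed"` (default) or `"otsu"`.
#' @param hough_min_votes Minimum accumulator support for a circle to count
#'   as detected (default 6).
#' @param close_brush_px Diameter of the disk structuring element for the
#'   morphological close (default 5, a radius-2 disk).
#' @return An object of class `marker_detector_config`.
#' @export
marker_detector_config <- function(median_kernel = 3L, min_component_px = 10L,
                                   hough_radius_range_px = c(3, 10),
                                   red_dominance_threshold = 60,
                                   dark_threshold = 0.25,
                                   binarize_method = c("fixed", "otsu"),
                                   hough_min_votes = 6,
                                   close_brush_px = 5L) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 3L || median_kernel %% 2L == 0L) {
    stop("'median_kernel' must be odd and >= 3", call. = FALSE)
  }
  if (min_component_px < 1L) stop("'min_component_px' must be >= 1", call. = FALSE)
  if (length(hough_radius_range_px) != 2L || any(hough_radius_range_px <= 0) ||
      diff(hough_radius_range_px) < 0) {
    stop("'hough_radius_range_px' must be positive and ordered", call. = FALSE)
  }
  structure(list(median_kernel = median_kernel,
                 min_component_px = as.integer(min_component_px),
                 hough_radius_range_px = hough_radius_range_px,
                 red_dominance_threshold = red_dominance_threshold,
                 dark_threshold = dark_threshold,
                 binarize_method = match.arg(binarize_method),
                 hough_min_votes = hough_min_votes,
                 close_brush_px = as.integer(close_brush_px)),
            class = "marker_detector_config")
}

marker_observation <- function(frame_index, agent, center = NULL,
                               radius = NA_real_, status = "detected") {
  structure(list(frame_index = frame_index, agent = agent,
                 center_px = center, radius_px = radius, status = status),
            class = "marker_observation")
}

#' @export
print.marker_observation <- function(x, ...) {
  if (x$status == "detected") {
    cat(sprintf("%s @ frame %d: (%.2f, %.2f) r=%.1f px\n", x$agent,
                x$frame_index, x$center_px[1], x$center_px[2], x$radius_px))
  } else {
    cat(sprintf("%s @ frame %d: missing\n", x$agent, x$frame_index))
  }
  invisible(x)
}

#' Remove small connected components from a binary mask
#'
#' Exactly those 8-connected components with pixel count at least `min_px`
#' survive; all others are zeroed. Idempotent.
#'
#' @param mask Binary (logical or 0/1) matrix.
#' @param min_px Minimum surviving component size in pixels.
#' @return Binary integer matrix of the same dimensions.
#' @export
remove_small_components <- function(mask, min_px) {
  m <- matrix(as.integer(mask != 0), nrow = nrow(mask))
  if (min_px <= 1L || !any(m > 0L)) return(m)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab %in% keep), nrow = nrow(mask))
}

# k x k median of a binary mask = majority vote over the window (exactly
# the median for {0,1} data), computed with an integral-image box sum.
# Single-pixel speckles vanish; solid disks survive.
binary_median <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  r <- (k - 1L) %/% 2L
  P <- matrix(0, h + 2L * r, w + 2L * r)
  P[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  I <- matrix(0, h + k, w + k)
  I[-1L, -1L] <- apply(P, 2L, cumsum)
  I[-1L, -1L] <- t(apply(I[-1L, -1L, drop = FALSE], 1L, cumsum))
  S <- I[(1:h) + k, (1:w) + k] - I[1:h, (1:w) + k] -
    I[(1:h) + k, 1:w] + I[1:h, 1:w]
  matrix(as.integer(S > (k * k) / 2), nrow = h)
}

# Circular Hough transform over a binary mask. Edge pixels (mask minus its
# erosion) vote for candidate centers at each radius; the strongest
# accumulator peak wins, with votes normalized by circumference so that the
# correct radius is preferred. Returns NULL when support is too weak.
hough_circle <- function(mask, radius_range, min_votes = 6) {
  pts <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(NULL)
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  edge <- which(mask > 0 & er == 0, arr.ind = TRUE)
  if (nrow(edge) == 0L) edge <- pts
  ex <- edge[, 2]; ey <- edge[, 1]  # x = col, y = row (1-based)

  radii <- seq(max(1, floor(radius_range[1])), ceiling(radius_range[2]))
  # accumulate only over the mask's neighborhood, not the whole frame
  rmax <- ceiling(radius_range[2])
  x_lo <- max(1L, min(ex) - rmax); x_hi <- min(ncol(mask), max(ex) + rmax)
  y_lo <- max(1L, min(ey) - rmax); y_hi <- min(nrow(mask), max(ey) + rmax)
  h <- y_hi - y_lo + 1L; w <- x_hi - x_lo + 1L
  ex <- ex - x_lo + 1L; ey <- ey - y_lo + 1L
  best <- NULL
  for (r in radii) {
    nang <- max(16L, ceiling(2 * pi * r))
    th <- seq(0, 2 * pi, length.out = nang + 1L)[-1L]
    cx <- round(rep(ex, each = nang) - r * cos(th))
    cy <- round(rep(ey, each = nang) - r * sin(th))
    ok <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
    if (!any(ok)) next
    acc_idx <- (cx[ok] - 1) * h + cy[ok]
    tab <- tabulate(acc_idx, nbins = h * w)
    peak <- which.max(tab)
    votes <- tab[peak]
    score <- votes / nang
    if (is.null(best) || score > best$score) {
      # sub-pixel refinement: vote-weighted centroid of near-peak cells
      px <- (peak - 1) %/% h + 1; py <- (peak - 1) %% h + 1
      nb_x <- pmax(1, pmin(w, px + rep(-2:2, each = 5)))
      nb_y <- pmax(1, pmin(h, py + rep(-2:2, times = 5)))
      nb_i <- (nb_x - 1) * h + nb_y
      wts <- tab[nb_i]
      wts[wts < 0.6 * votes] <- 0
      if (sum(wts) > 0) {
        cxr <- sum(nb_x * wts) / sum(wts)
        cyr <- sum(nb_y * wts) / sum(wts)
      } else {
        cxr <- px; cyr <- py
      }
      best <- list(center = c(x = cxr - 1 + (x_lo - 1L), y = cyr - 1 + (y_lo - 1L)),
                   radius = r, votes = votes, score = score)
    }
  }
  if (is.null(best) || best$votes < min_votes) return(NULL)
  best
}

# Minimum enclosing circle of a point set (columns x, y), via candidate
# circles through pairs and triples of convex hull points.
min_enclosing_circle <- function(xy) {
  if (nrow(xy) == 1L) return(list(center = xy[1, ], radius = 0))
  hull <- xy[unique(grDevices::chull(xy)), , drop = FALSE]
  n <- nrow(hull)
  covers <- function(c0, r0) all(sqrt((hull[, 1] - c0[1])^2 +
                                        (hull[, 2] - c0[2])^2) <= r0 + 1e-9)
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    c0 <- (hull[i, ] + hull[j, ]) / 2
    r0 <- sqrt(sum((hull[i, ] - hull[j, ])^2)) / 2
    if (covers(c0, r0) && (is.null(best) || r0 < best$radius)) {
      best <- list(center = c0, radius = r0)
    }
  }
  if (is.null(best) && n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- hull[i, ]; b <- hull[j, ]; cc <- hull[k, ]
      d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
                  cc[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- ((sum(a^2)) * (b[2] - cc[2]) + (sum(b^2)) * (cc[2] - a[2]) +
               (sum(cc^2)) * (a[2] - b[2])) / d
      uy <- ((sum(a^2)) * (cc[1] - b[1]) + (sum(b^2)) * (a[1] - cc[1]) +
               (sum(cc^2)) * (b[1] - a[1])) / d
      c0 <- c(ux, uy)
      r0 <- sqrt(sum((a - c0)^2))
      if (covers(c0, r0) && (is.null(best) || r0 < best$radius)) {
        best <- list(center = c0, radius = r0)
      }
    }
  }
  best
}

#' Detect the prey marker (bright red blob) in one frame
#'
#' Pipeline: red-dominance mask, 3 x 3 median filter, circular Hough
#' transform over the configured radius range; the strongest circle's center
#' is reported. Status is `"missing"` when no circle gathers enough
#' accumulator support.
#'
#' @param frame `[h, w, 3]` numeric array in `[0, 1]`.
#' @param config A [marker_detector_config()].
#' @param frame_index Frame number recorded in the observation.
#' @return A `marker_observation` (center in 0-based px coordinates).
#' @export
detect_prey <- function(frame, config = marker_detector_config(),
                        frame_index = 1L) {
  if (length(dim(frame)) != 3L || dim(frame)[3] < 3L) {
    stop("detect_prey needs a 3-channel frame", call. = FALSE)
  }
  thr <- config$red_dominance_threshold / 255
  mask <- (frame[, , 1] - pmax(frame[, , 2], frame[, , 3])) > thr
  mask <- matrix(as.numeric(mask), nrow = dim(frame)[1])
  if (!any(mask > 0)) return(marker_observation(frame_index, "prey", status = "missing"))
  mask <- binary_median(mask, config$median_kernel)
  circ <- hough_circle(mask, config$hough_radius_range_px, config$hough_min_votes)
  if (is.null(circ)) return(marker_observation(frame_index, "prey", status = "missing"))
  marker_observation(frame_index, "prey", center = circ$center,
                     radius = circ$radius)
}

#' Detect the predator marker (black dot) in one frame
#'
#' Pipeline: binarize with dark-object foreground, remove connected
#' components smaller than `min_component_px`, morphological close (dilation
#' then erosion), then fit the minimum enclosing circle of the largest
#' surviving component.
#'
#' @inheritParams detect_prey
#' @return A `marker_observation` (center in 0-based px coordinates).
#' @export
detect_predator <- function(frame, config = marker_detector_config(),
                            frame_index = 1L) {
  gray <- if (length(dim(frame)) == 3L) {
    (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  } else frame
  thr <- if (config$binarize_method == "otsu") {
    EBImage::otsu(EBImage::Image(gray))
  } else config$dark_threshold
  mask <- matrix(as.integer(gray < thr), nrow = nrow(gray))
  mask <- remove_small_components(mask, config$min_component_px)
  if (!any(mask > 0L)) {
    return(marker_observation(frame_index, "predator", status = "missing"))
  }
  brush <- EBImage::makeBrush(config$close_brush_px, "disc")
  mask <- EBImage::closing(mask, brush)
  mask <- matrix(as.integer(mask > 0), nrow = nrow(gray))
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L) {
    return(marker_observation(frame_index, "predator", status = "missing"))
  }
  comp <- which.max(sizes)
  pts <- which(lab == comp, arr.ind = TRUE)
  xy <- cbind(x = pts[, 2] - 1, y = pts[, 1] - 1)
  fit <- min_enclosing_circle(xy)
  marker_observation(frame_index, "predator", center = c(x = fit$center[[1]],
                                                         y = fit$center[[2]]),
                     radius = fit$radius)
}

#' Track both markers over a full trial
#'
#' Runs [detect_prey()] and [detect_predator()] on every frame. Frames where
#' a marker is not found carry the last detected position forward but remain
#' flagged `"missing"`; leading missing frames take the first later
#' detection.
#'
#' @param frames List of `[h, w, 3]` arrays, or a [trial_renderer()] (frames
#'   are then rendered one at a time and never all held in memory).
#' @param config A [marker_detector_config()].
#' @param progress_every Print a progress line every this many frames
#'   (0 = silent).
#' @return Data frame with one row per agent per frame: `frame`, `agent`,
#'   `x_px`, `y_px`, `radius_px`, `status`.
#' @export
track_trial <- function(frames, config = marker_detector_config(),
                        progress_every = 0L) {
  streaming <- inherits(frames, "trial_renderer")
  n <- if (streaming) frames$n_frames else length(frames)
  if (n == 0L) stop("empty frame sequence", call. = FALSE)
  res <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    fr <- if (streaming) frames$frame(i) else frames[[i]]
    op <- detect_prey(fr, config, i)
    od <- detect_predator(fr, config, i)
    res[[2L * i - 1L]] <- op
    res[[2L * i]] <- od
    if (progress_every > 0L && i %% progress_every == 0L) {
      message(sprintf("tracked %d/%d frames", i, n))
    }
  }
  df <- do.call(rbind, lapply(res, function(o) data.frame(
    frame = o$frame_index, agent = o$agent,
    x_px = if (is.null(o$center_px)) NA_real_ else o$center_px[[1]],
    y_px = if (is.null(o$center_px)) NA_real_ else o$center_px[[2]],
    radius_px = o$radius_px, status = o$status)))
  # hold-last-position fill, per agent
  for (ag in c("prey", "predator")) {
    sel <- which(df$agent == ag)
    x <- df$x_px[sel]; y <- df$y_px[sel]
    lastx <- NA_real_; lasty <- NA_real_
    for (j in seq_along(sel)) {
      if (is.na(x[j])) { x[j] <- lastx; y[j] <- lasty }
      else { lastx <- x[j]; lasty <- y[j] }
    }
    # leading gap: backfill from the first detection
    if (anyNA(x) && any(!is.na(x))) {
      first <- which(!is.na(x))[1L]
      x[seq_len(first - 1L)] <- x[first]; y[seq_len(first - 1L)] <- y[first]
    }
    df$x_px[sel] <- x; df$y_px[sel] <- y
  }
  rownames(df) <- NULL
  df
}

#' Write per-frame marker observations to CSV
#' @param observations Data frame from [track_trial()].
#' @param path Output CSV path.
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
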