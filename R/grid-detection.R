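# Unsupervised recovery of hexagonal grid cell centers from a board image:
# Canny edge map -> closed boundary tracing (connected regions enclosed by
# edges) -> per-region centroid -> lattice-consistency check and repair ->
# matching against the physical grid, yielding the pixel/cm calibration.

#' Grid detector configuration
#'
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   gradient dynamic range (defaults 0.1 / 0.3).
#' @param corner_angles Corner bearing list retained as a diagnostic field
#'   (degrees; default `c(45, 90, 135, 225, 270, 315)`). The primary
#'   consistency criterion is nearest-neighbor center spacing, which is
#'   well-defined for flat-top hexagon centers at any orientation.
#' @param corner_distance_tolerance Relative deviation from the expected
#'   center spacing beyond which a center is deemed noisy (default 0.15).
#' @param min_region_px Traced regions smaller than this are discarded as
#'   noise (default 20).
#' @param blur_sigma Gaussian sigma for the edge detector (default 1).
#' @return An object of class `grid_detector_config`.
#' @export
grid_detector_config <- function(canny_low = 0.1, canny_high = 0.3,
                                 corner_angles = c(45, 90, 135, 225, 270, 315),
                                 corner_distance_tolerance = 0.15,
                                 min_region_px = 20L, blur_sigma = 1) {
  stopifnot(canny_low > 0, canny_high > canny_low, canny_high <= 1,
            corner_distance_tolerance > 0, corner_distance_tolerance < 1)
  structure(list(canny_low = canny_low, canny_high = canny_high,
                 corner_angles = corner_angles,
                 corner_distance_tolerance = corner_distance_tolerance,
                 min_region_px = as.integer(min_region_px),
                 blur_sigma = blur_sigma),
            class = "grid_detector_config")
}

# Label the regions enclosed by the edge map and return their centroids.
# The image-border-touching background region and low-solidity slivers
# (the corridor between the double edges of a traced line) are discarded.
enclosed_region_centroids <- function(edges, min_region_px) {
  interior <- matrix(as.integer(edges == 0L), nrow(edges))
  lab <- EBImage::bwlabel(interior)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  idx <- which(lab > 0L & !(lab %in% border_labs))
  if (length(idx) == 0L) return(NULL)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  f <- factor(l)
  area <- as.numeric(tapply(rows, f, length))
  cx <- as.numeric(tapply(cols, f, mean))
  cy <- as.numeric(tapply(rows, f, mean))
  bw <- as.numeric(tapply(cols, f, max)) - as.numeric(tapply(cols, f, min)) + 1
  bh <- as.numeric(tapply(rows, f, max)) - as.numeric(tapply(rows, f, min)) + 1
  data.frame(x = cx - 1, y = cy - 1,    # 0-based px
             area = area, fill = area / (bw * bh))
}

#' Check lattice consistency of detected centers and repair noisy ones
#'
#' A center is consistent when at least two other centers sit at the
#' expected lattice spacing (within the configured relative tolerance).
#' Inconsistent centers are replaced by the position implied by the ideal
#' triangular lattice fitted to the consistent centers, and flagged.
#'
#' @param centers_px Matrix of detected centers (columns x, y, 0-based px).
#' @param expected_spacing_px Expected neighbor center spacing in px
#'   (`sqrt(3) * cell_size * px_per_cm` for flat-top hexagons).
#' @param config A [grid_detector_config()].
#' @return List with `centers_px` (same dimensions, noisy rows replaced) and
#'   `repaired_flags` (logical).
#' @export
validate_and_repair <- function(centers_px, expected_spacing_px,
                                config = grid_detector_config()) {
  stopifnot(expected_spacing_px > 0)
  centers_px <- as.matrix(centers_px)[, 1:2, drop = FALSE]
  n <- nrow(centers_px)
  tol <- config$corner_distance_tolerance
  s <- expected_spacing_px
  d <- as.matrix(stats::dist(centers_px))
  near <- d >= s * (1 - tol) & d <= s * (1 + tol)
  diag(near) <- FALSE
  consistent <- rowSums(near) >= 2L
  flags <- !consistent
  if (!any(flags)) return(list(centers_px = centers_px, repaired_flags = flags))
  if (sum(consistent) < 3L) {
    stop("cannot repair: fewer than 3 consistent anchor centers", call. = FALSE)
  }
  # fit the ideal flat-top center lattice (a triangular lattice with spacing
  # s, axis-aligned: camera is perpendicular to the board)
  B <- cbind(c(0, s), c(s * sqrt(3) / 2, s / 2))
  p0 <- centers_px[which(consistent)[1L], ]
  frac <- t(solve(B, t(sweep(centers_px, 2, p0))))
  n_int <- round(frac[consistent, , drop = FALSE])
  pred <- t(B %*% t(n_int)) + rep(p0, each = nrow(n_int))
  resid <- centers_px[consistent, , drop = FALSE] - pred
  p0 <- p0 + colMeans(resid)
  frac <- t(solve(B, t(sweep(centers_px, 2, p0))))
  occupied <- unique(paste(round(frac[consistent, 1]),
                           round(frac[consistent, 2])))
  for (i in which(flags)) {
    f <- frac[i, ]
    cand <- expand.grid(a = round(f[1]) + (-2:2), b = round(f[2]) + (-2:2))
    key <- paste(cand$a, cand$b)
    cand <- cand[!(key %in% occupied), , drop = FALSE]
    pos <- t(B %*% t(as.matrix(cand))) + rep(p0, each = nrow(cand))
    dd <- (pos[, 1] - centers_px[i, 1])^2 + (pos[, 2] - centers_px[i, 2])^2
    j <- which.min(dd)
    centers_px[i, ] <- pos[j, ]
    occupied <- c(occupied, paste(cand$a[j], cand$b[j]))
  }
  list(centers_px = centers_px, repaired_flags = flags)
}

#' Least-squares pixel-per-cm calibration from matched centers
#'
#' The scale that best maps cm pairwise spacings onto pixel pairwise
#' spacings in the least-squares sense.
#'
#' @param centers_px Matrix of pixel centers (columns x, y).
#' @param centers_cm Matrix of the corresponding physical centers in cm.
#' @return Positive scalar px/cm.
#' @export
calibrate <- function(centers_px, centers_cm) {
  centers_px <- as.matrix(centers_px); centers_cm <- as.matrix(centers_cm)
  n <- nrow(centers_px)
  if (n < 2L || nrow(centers_cm) != n) {
    stop("need at least 2 matched centers", call. = FALSE)
  }
  dpx <- stats::dist(centers_px[, 1:2])
  dcm <- stats::dist(centers_cm[, 1:2])
  if (sum(dcm^2) == 0) stop("degenerate: all centers coincident", call. = FALSE)
  s <- sum(dpx * dcm) / sum(dcm^2)
  if (s <= 0) stop("degenerate calibration", call. = FALSE)
  s
}

# Refine a lattice spacing estimate by least-squares fit of the detections
# to integer triangular-lattice indices; points far off the lattice
# (spurious detections) are dropped after the first pass.
refine_spacing <- function(pts, spacing) {
  for (it in 1:3) {
    B <- cbind(c(0, spacing), c(spacing * sqrt(3) / 2, spacing / 2))
    p0 <- pts[1, ]
    n <- round(t(solve(B, t(sweep(pts, 2, p0)))))
    V <- t(B %*% t(n))
    resid <- sweep(pts, 2, p0) - V
    keep <- sqrt(rowSums(resid^2)) <= 0.25 * spacing
    if (sum(keep) >= 6L) {
      pts <- pts[keep, , drop = FALSE]
      n <- n[keep, , drop = FALSE]
      V <- V[keep, , drop = FALSE]
    }
    Vc <- sweep(V, 2, colMeans(V))
    Pc <- sweep(pts, 2, colMeans(pts))
    denom <- sum(Vc * Vc)
    if (denom == 0) break
    spacing <- spacing * sum(Vc * Pc) / denom
  }
  spacing
}

# LS fit of the axis-aligned affine map x_px = ox + s * x_cm,
# y_px = oy - s * y_cm (single scale; y flips between cm-up and px-down).
fit_affine <- function(px, cm) {
  A <- rbind(cbind(cm[, 1], 1, 0), cbind(-cm[, 2], 0, 1))
  b <- c(px[, 1], px[, 2])
  cf <- solve(crossprod(A), crossprod(A, b))
  list(px_per_cm = cf[1], ox = cf[2], oy = cf[3])
}

#' Detect hexagonal grid cell centers in a board image
#'
#' Pipeline: Canny edge map, tracing of the closed hexagon boundaries
#' (connected enclosed regions), per-boundary centroid as the cell center,
#' lattice-consistency check with repair of noisy centers, then matching of
#' the detected centers to the physical grid implied by `spec`, which yields
#' the px/cm calibration. Grid cells with no acceptable detected center are
#' filled in at their lattice-implied position and flagged repaired.
#'
#' @param image `[h, w, 3]` array or grayscale matrix of the board.
#' @param spec The board's [hex_grid_spec()].
#' @param config A [grid_detector_config()].
#' @return An object of class `grid_detection_result`: list with
#'   `centers_px` (one row per grid cell, in cell order), `repaired_flags`,
#'   `px_per_cm`, `matched_grid` (the grid with `x_px`, `y_px` columns
#'   added), `calibration`, and `n_detected` (raw detections before
#'   matching).
#' @export
detect_grid_centers <- function(image, spec, config = grid_detector_config()) {
  gray <- if (length(dim(image)) == 3L) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else image
  edges <- canny_edges(gray, config$canny_low, config$canny_high,
                       config$blur_sigma)
  n_edge_px <- sum(edges)
  regions <- enclosed_region_centroids(edges, config$min_region_px)
  if (!is.null(regions)) {
    regions <- regions[regions$area >= config$min_region_px &
                         regions$fill >= 0.5, , drop = FALSE]
    if (nrow(regions) >= 4L) {
      med_area <- stats::median(regions$area)
      regions <- regions[regions$area >= 0.4 * med_area &
                           regions$area <= 1.8 * med_area, , drop = FALSE]
    }
  }
  if (is.null(regions) || nrow(regions) < 3L) {
    stop(sprintf("grid detection failed: no closed hexagon boundaries (%d edge pixels)",
                 n_edge_px), call. = FALSE)
  }
  centers <- as.matrix(regions[, c("x", "y")])

  # expected spacing: nearest-neighbor distance among detections
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  spacing_px <- stats::median(apply(d, 1, min))
  vr <- validate_and_repair(centers, spacing_px, config)

  # match to the physical grid: initial scale from spacing, translation from
  # centroids, then one LS refinement over matched pairs
  grid <- hex_grid(spec)
  cm <- as.matrix(grid$cells[, c("x_cm", "y_cm")])
  spacing_ref <- refine_spacing(vr$centers_px, spacing_px)
  s0 <- spacing_ref / (sqrt(3) * spec$cell_size)
  # translation: try anchoring a central detection to each nearby grid cell
  # and keep the candidate with the most (then tightest) matches. Robust to
  # missing or spurious detections, unlike a centroid match.
  gpx <- cbind(s0 * cm[, 1], -s0 * cm[, 2])
  ctr <- colMeans(vr$centers_px)
  anchor <- which.min((vr$centers_px[, 1] - ctr[1])^2 +
                        (vr$centers_px[, 2] - ctr[2])^2)
  pa <- vr$centers_px[anchor, ]
  dctr <- sqrt((gpx[, 1] - mean(gpx[, 1]))^2 + (gpx[, 2] - mean(gpx[, 2]))^2)
  cand_cells <- which(dctr <= 3 * spacing_ref)
  best <- NULL
  for (j in cand_cells) {
    off <- pa - gpx[j, ]
    dmat <- outer(gpx[, 1] + off[1], vr$centers_px[, 1], "-")^2 +
      outer(gpx[, 2] + off[2], vr$centers_px[, 2], "-")^2
    dmin <- sqrt(apply(dmat, 1, min))
    hit <- dmin <= 0.25 * spacing_ref
    score <- sum(hit)
    resid <- if (score > 0) mean(dmin[hit]) else Inf
    if (is.null(best) || score > best$score ||
        (score == best$score && resid < best$resid)) {
      best <- list(off = off, score = score, resid = resid)
    }
  }
  aff <- list(px_per_cm = s0, ox = best$off[1], oy = best$off[2])
  for (pass in 1:2) {
    cal <- structure(aff, class = "board_calibration")
    pred <- cm_to_px(cal, cm)
    nn <- vapply(seq_len(nrow(pred)), function(i) {
      dd <- (vr$centers_px[, 1] - pred[i, 1])^2 +
        (vr$centers_px[, 2] - pred[i, 2])^2
      j <- which.min(dd)
      if (sqrt(dd[j]) <= 0.35 * spacing_px) j else NA_integer_
    }, integer(1))
    ok <- !is.na(nn)
    if (sum(ok) < 3L) {
      stop("grid detection failed: could not match detections to the grid",
           call. = FALSE)
    }
    aff <- fit_affine(vr$centers_px[nn[ok], , drop = FALSE],
                      cm[ok, , drop = FALSE])
  }
  cal <- structure(aff, class = "board_calibration")
  pred <- cm_to_px(cal, cm)
  centers_out <- pred
  flags_out <- rep(TRUE, nrow(cm))
  centers_out[ok, ] <- vr$centers_px[nn[ok], ]
  flags_out[ok] <- vr$repaired_flags[nn[ok]]
  grid$cells$x_px <- centers_out[, 1]
  grid$cells$y_px <- centers_out[, 2]

  structure(list(centers_px = centers_out, repaired_flags = flags_out,
                 px_per_cm = aff$px_per_cm, matched_grid = grid,
                 calibration = cal, n_detected = nrow(centers),
                 spacing_px = spacing_px),
            class = "grid_detection_result")
}

#' @export
print.grid_detection_result <- function(x, ...) {
  cat(sprintf(
    "grid_detection_result: %d cells (%d raw detections, %d repaired), %.3f px/cm\n",
    nrow(x$centers_px), x$n_detected, sum(x$repaired_flags), x$px_per_cm))
  invisible(x)
}

#' Export a grid detection result as JSON
#' @param result A `grid_detection_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
detection_to_json <- function(result, path = NULL) {
  obj <- list(px_per_cm = result$px_per_cm,
              centers = data.frame(x_px = result$centers_px[, 1],
                                   y_px = result$centers_px[, 2],
                                   repaired = result$repaired_flags))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
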