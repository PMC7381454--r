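# Canny edge detector on a grayscale matrix: Gaussian smoothing, Sobel
# gradients, non-maximum suppression along the quantized gradient direction,
# and two-threshold hysteresis (weak edges survive only when 8-connected to a
# strong edge). Thresholds are fractions of the gradient dynamic range.

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

canny_edges <- function(gray, low = 0.1, high = 0.3, sigma = 1) {
  stopifnot(is.matrix(gray), low > 0, high > low, high <= 1)
  g <- EBImage::gblur(gray, sigma = sigma)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1)) / 4
  gx <- EBImage::filter2(g, kx)
  gy <- EBImage::filter2(g, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(0L, nrow(gray), ncol(gray)))
  dir4 <- (round(atan2(gy, gx) / (pi / 4)) %% 4)

  # non-maximum suppression: compare against the two neighbors along the
  # gradient direction (0 = horizontal gradient -> left/right neighbors, etc.)
  nms <- mag
  offs <- list(`0` = list(c(0, 1), c(0, -1)),       # gradient E-W
               `1` = list(c(1, 1), c(-1, -1)),       # NE-SW
               `2` = list(c(1, 0), c(-1, 0)),        # N-S
               `3` = list(c(1, -1), c(-1, 1)))       # NW-SE
  for (d in 0:3) {
    o <- offs[[as.character(d)]]
    n1 <- shift_mat(mag, o[[1]][1], o[[1]][2])
    n2 <- shift_mat(mag, o[[2]][1], o[[2]][2])
    kill <- dir4 == d & (mag < n1 | mag < n2)
    nms[kill] <- 0
  }

  mx <- max(nms)
  strong <- nms >= high * mx
  weak <- nms >= low * mx
  lab <- EBImage::bwlabel(matrix(as.integer(weak), nrow(gray)))
  keep <- unique(lab[strong & lab > 0])
  matrix(as.integer(lab %in% keep & lab > 0), nrow(gray))
}
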