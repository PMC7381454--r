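# Prey movement pattern generators: predictable (hex-quantized sinusoid),
# random (drifting lattice walk), and semi-random (alternating segments of
# the two). All generators emit one grid cell per beat with consecutive
# cells identical or lattice-adjacent -- the metronome constraint of one
# hexagon step per beat.

#' Pattern specification
#'
#' @param kind `"predictable"`, `"semi_random"` or `"random"`.
#' @param frequency_hz Sinusoid frequency for the predictable pattern
#'   (default 0.19 Hz, the value found to make the wave form prominent).
#' @param amplitude_cm Sinusoid amplitude (default 7.5 cm, i.e. 2.5 hexagon
#'   widths at 1.5 cm cell size).
#' @param bpm Metronome rate pacing the movement (default 70).
#' @param seed Integer seed; required for the stochastic kinds.
#' @param drift_bias Probability of resampling a leftward move in the random
#'   walk, enforcing net left-to-right progression (default 0.5).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(kind = c("predictable", "semi_random", "random"),
                         frequency_hz = 0.19, amplitude_cm = 7.5, bpm = 70,
                         seed = NULL, drift_bias = 0.5) {
  kind <- match.arg(kind)
  if (kind == "predictable" && (frequency_hz <= 0 || amplitude_cm < 0)) {
    stop("predictable pattern needs frequency_hz > 0 and amplitude_cm >= 0",
         call. = FALSE)
  }
  if (kind != "predictable" && is.null(seed)) {
    stop(sprintf("kind '%s' requires a seed", kind), call. = FALSE)
  }
  structure(list(kind = kind, frequency_hz = frequency_hz,
                 amplitude_cm = amplitude_cm, bpm = bpm,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 drift_bias = drift_bias),
            class = "pattern_spec")
}

#' Amplitude expressed in hexagon widths
#'
#' Unit conversion of the sinusoid amplitude: cm divided by the cell width
#' `2 * cell_size`. 7.5 cm at 1.5 cm cells is 2.5 hexagons.
#'
#' @param amplitude_cm Amplitude in cm.
#' @param cell_size Hexagon circumradius in cm.
#' @return Amplitude in hexagon-width units.
#' @export
amplitude_in_hex_widths <- function(amplitude_cm, cell_size) {
  amplitude_cm / cell_dimensions(cell_size)[["width"]]
}

# The ideal continuous sinusoid path: x advances one cell width per beat
# rightward from the start cell; y = y0 + A sin(2 pi f t), with beat k at
# t = k * 60 / bpm. Returned as a dense polyline in cm.
sinusoid_ideal_path <- function(spec, grid, start_cell) {
  gs <- grid$spec
  w <- cell_dimensions(gs$cell_size)[["width"]]
  x0 <- grid$cells$x_cm[start_cell]; y0 <- grid$cells$y_cm[start_cell]
  x_end <- gs$origin[1] + gs$board_width - gs$cell_size
  if (spec$amplitude_cm > gs$board_height / 2) {
    stop("amplitude exceeds board half-height", call. = FALSE)
  }
  # x(t) = x0 + w * (t * bpm / 60); sample densely along x
  xs <- seq(x0, max(x0, x_end), by = gs$cell_size / 20)
  ts <- (xs - x0) / w * 60 / spec$bpm
  ys <- y0 + spec$amplitude_cm * sin(2 * pi * spec$frequency_hz * ts)
  lo <- gs$origin[2] + gs$cell_size
  hi <- gs$origin[2] + gs$board_height - gs$cell_size
  cbind(x = xs, y = pmin(pmax(ys, lo), hi))
}

# Snap a dense polyline to a cell sequence with all consecutive cells
# lattice-adjacent: snap every sample, drop repeats, then bridge any
# non-adjacent jump by greedy neighbor steps.
quantize_path <- function(path_cm, grid) {
  cells <- nearest_cell(grid, path_cm)
  cells <- cells[c(TRUE, diff(cells) != 0)]
  out <- cells[1]
  for (k in seq_along(cells)[-1]) {
    target <- cells[k]
    while (out[length(out)] != target) {
      cur <- out[length(out)]
      nb <- hex_neighbors(grid, cur)
      if (target %in% nb) {
        out <- c(out, target)
      } else {
        d2 <- (grid$cells$x_cm[nb] - grid$cells$x_cm[target])^2 +
          (grid$cells$y_cm[nb] - grid$cells$y_cm[target])^2
        out <- c(out, nb[which.min(d2)])
      }
    }
  }
  out
}

#' Predictable (hex-quantized sinusoid) prey pattern
#'
#' The ideal path advances one cell width per beat rightward while the
#' vertical coordinate follows `y0 + A sin(2 pi f t)`; the path is densely
#' sampled, snapped to nearest cells, and bridged so every consecutive pair
#' of cells is lattice-adjacent. With amplitude 0 this degenerates to a
#' straight rightward march. If the quantized path ends (right board edge)
#' before `n_beats`, the prey stays on its final cell.
#'
#' @param spec A [pattern_spec()] with `kind = "predictable"`.
#' @param grid A [hex_grid()].
#' @param n_beats Number of beats to emit.
#' @param start_cell Row index of the starting cell (default: leftmost cell
#'   nearest the board's vertical center).
#' @return Integer vector of `n_beats` cell row indices.
#' @export
sinusoid_pattern <- function(spec, grid, n_beats, start_cell = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "predictable") stop("spec$kind must be 'predictable'", call. = FALSE)
  if (is.null(start_cell)) start_cell <- default_start_cell(grid)
  path <- sinusoid_ideal_path(spec, grid, start_cell)
  cells <- quantize_path(path, grid)
  pad_or_trim(cells, n_beats)
}

default_start_cell <- function(grid) {
  mid_y <- grid$spec$origin[2] + grid$spec$board_height / 2
  left <- which(grid$cells$q == min(grid$cells$q))
  left[which.min(abs(grid$cells$y_cm[left] - mid_y))]
}

pad_or_trim <- function(cells, n_beats) {
  if (length(cells) >= n_beats) return(cells[seq_len(n_beats)])
  c(cells, rep(cells[length(cells)], n_beats - length(cells)))
}

#' Random prey pattern (drifting lattice walk)
#'
#' At each beat the prey moves to a uniformly chosen lattice neighbor;
#' moves off the board are excluded and leftward moves are resampled with
#' probability `drift_bias`, giving net left-to-right progression.
#' Deterministic given the seed.
#'
#' @inheritParams sinusoid_pattern
#' @param spec A [pattern_spec()] with `kind = "random"` and a seed.
#' @return Integer vector of `n_beats` cell row indices.
#' @export
random_pattern <- function(spec, grid, n_beats, start_cell = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "random") stop("spec$kind must be 'random'", call. = FALSE)
  if (is.null(start_cell)) start_cell <- default_start_cell(grid)
  if (start_cell < 1L || start_cell > nrow(grid$cells)) {
    stop("start cell not in grid", call. = FALSE)
  }
  with_local_seed(spec$seed, {
    out <- integer(n_beats)
    out[1] <- start_cell
    for (k in seq_len(n_beats - 1L)) {
      cur <- out[k]
      repeat {
        nb <- hex_neighbors(grid, cur)
        cand <- nb[sample.int(length(nb), 1L)]
        leftward <- grid$cells$x_cm[cand] < grid$cells$x_cm[cur]
        if (!leftward || stats::runif(1) >= spec$drift_bias) break
      }
      out[k + 1L] <- cand
    }
    out
  })
}

#' Semi-random prey pattern (alternating sinusoid and random segments)
#'
#' Alternates segments that follow the predictable sinusoid reference path
#' with random-walk segments; segment lengths are geometric with the given
#' mean. During sinusoid segments the prey steps along the reference path
#' (re-entering it at the nearest path cell after a random excursion), so in
#' the `segment_mean -> Inf` limit with a sinusoid segment first the output
#' equals [sinusoid_pattern()]. All steps are lattice-adjacent;
#' deterministic given the seed.
#'
#' @inheritParams sinusoid_pattern
#' @param spec A [pattern_spec()] with `kind = "semi_random"` and a seed.
#' @param segment_mean Mean segment length in beats (default 6).
#' @return Integer vector of `n_beats` cell row indices.
#' @export
semirandom_pattern <- function(spec, grid, n_beats, segment_mean = 6,
                               start_cell = NULL) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "semi_random") stop("spec$kind must be 'semi_random'", call. = FALSE)
  if (is.null(start_cell)) start_cell <- default_start_cell(grid)
  sin_spec <- pattern_spec("predictable", frequency_hz = spec$frequency_hz,
                           amplitude_cm = spec$amplitude_cm, bpm = spec$bpm)
  ref <- quantize_path(sinusoid_ideal_path(sin_spec, grid, start_cell), grid)
  with_local_seed(spec$seed, {
    out <- integer(n_beats)
    out[1] <- start_cell
    mode_sin <- TRUE
    left <- seg_len(segment_mean)
    ref_pos <- 1L
    k <- 1L
    while (k < n_beats) {
      cur <- out[k]
      if (left == 0L) {
        mode_sin <- !mode_sin
        left <- seg_len(segment_mean)
      }
      if (mode_sin) {
        # step along (or back toward) the reference path
        d2 <- (grid$cells$x_cm[ref] - grid$cells$x_cm[cur])^2 +
          (grid$cells$y_cm[ref] - grid$cells$y_cm[cur])^2
        nearest_ref <- which.min(d2)
        target <- ref[min(nearest_ref + 1L, length(ref))]
        if (target == cur) {
          nxt <- cur
        } else {
          nb <- hex_neighbors(grid, cur)
          if (target %in% nb) nxt <- target
          else {
            dd <- (grid$cells$x_cm[nb] - grid$cells$x_cm[target])^2 +
              (grid$cells$y_cm[nb] - grid$cells$y_cm[target])^2
            nxt <- nb[which.min(dd)]
          }
        }
      } else {
        repeat {
          nb <- hex_neighbors(grid, cur)
          nxt <- nb[sample.int(length(nb), 1L)]
          leftward <- grid$cells$x_cm[nxt] < grid$cells$x_cm[cur]
          if (!leftward || stats::runif(1) >= spec$drift_bias) break
        }
      }
      k <- k + 1L
      out[k] <- nxt
      left <- left - 1L
    }
    out
  })
}

# Geometric segment length with the given mean (at least 1 beat).
seg_len <- function(mean_len) {
  if (!is.finite(mean_len)) return(.Machine$integer.max)
  1L + stats::rgeom(1L, prob = 1 / max(mean_len, 1))
}
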