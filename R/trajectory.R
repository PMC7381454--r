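# Spatiotemporal cropping, beat-synchronized sampling, snapping of marker
# detections to hexagonal grid centers, and the predator-prey distance metric.

#' Trial video metadata
#'
#' @param fps Frames per second of the recording (default 50).
#' @param bpm Metronome rate in beats per minute that paces the agents
#'   (default 70: one hexagon step per beat).
#' @param roi_px Optional region of interest `c(x, y, w, h)` in 0-based pixel
#'   coordinates, or `NULL` for the full frame.
#' @param start_frame,end_frame 1-based inclusive trial bounds (manually
#'   chosen in practice to exclude the stationary lead-in/out).
#' @return An object of class `trial_video_meta`.
#' @export
trial_video_meta <- function(fps = 50, bpm = 70, roi_px = NULL,
                             start_frame = 1L, end_frame = NULL) {
  stopifnot(fps > 0, bpm > 0)
  if (!is.null(end_frame) && start_frame >= end_frame + 1L) {
    stop("start_frame must not exceed end_frame", call. = FALSE)
  }
  structure(list(fps = fps, bpm = bpm, roi_px = roi_px,
                 start_frame = as.integer(start_frame),
                 end_frame = if (is.null(end_frame)) NULL else as.integer(end_frame)),
            class = "trial_video_meta")
}

#' Frames per metronome beat
#'
#' At the study settings (50 fps, 70 bpm) this is 50 * 60 / 70 = 42.857...,
#' deliberately non-integer; beat sampling rounds to the nearest frame.
#'
#' @param fps Frames per second.
#' @param bpm Beats per minute.
#' @return `fps * 60 / bpm`.
#' @export
frames_per_beat <- function(fps, bpm) {
  if (!is.numeric(fps) || !is.numeric(bpm) || fps <= 0 || bpm <= 0) {
    stop("fps and bpm must be positive", call. = FALSE)
  }
  fps * 60 / bpm
}

#' Crop a frame sequence in space and time
#'
#' Restricts frames to `meta$roi_px` and keeps frames
#' `start_frame:end_frame` inclusive.
#'
#' @param frames List of `[h, w, 3]` arrays (or matrices).
#' @param meta A [trial_video_meta()] with `end_frame` set.
#' @return List of cropped frames of length `end_frame - start_frame + 1`.
#' @export
crop_spatiotemporal <- function(frames, meta) {
  stopifnot(inherits(meta, "trial_video_meta"))
  if (is.null(meta$end_frame)) stop("meta$end_frame must be set", call. = FALSE)
  if (meta$start_frame > meta$end_frame) {
    stop("empty time window: start_frame > end_frame", call. = FALSE)
  }
  if (meta$start_frame < 1L || meta$end_frame > length(frames)) {
    stop("time window outside the frame sequence", call. = FALSE)
  }
  sel <- frames[meta$start_frame:meta$end_frame]
  if (is.null(meta$roi_px)) return(sel)
  roi <- meta$roi_px
  d <- dim(sel[[1]])
  if (roi[1] < 0 || roi[2] < 0 || roi[1] + roi[3] > d[2] || roi[2] + roi[4] > d[1]) {
    stop("ROI outside frame bounds", call. = FALSE)
  }
  rows <- (roi[2] + 1L):(roi[2] + roi[4])
  cols <- (roi[1] + 1L):(roi[1] + roi[3])
  lapply(sel, function(f) {
    if (length(dim(f)) == 3L) f[rows, cols, , drop = FALSE] else f[rows, cols, drop = FALSE]
  })
}

#' Reduce per-frame observations to one sample per metronome beat
#'
#' Beat `k` (0-based) is taken from the observation at the frame nearest
#' `start + k * frames_per_beat`; the number of beats is
#' `floor((end - start) / frames_per_beat) + 1`.
#'
#' @param observations Data frame as produced by [track_trial()] for a single
#'   agent: columns `frame`, `x_px`, `y_px`, `status`.
#' @param meta A [trial_video_meta()]. `start_frame`/`end_frame` default to
#'   the observation range.
#' @return Data frame with columns `beat`, `frame`, `x_px`, `y_px`, `status`.
#' @export
sample_beats <- function(observations, meta = trial_video_meta()) {
  if (nrow(observations) == 0L) stop("no observations", call. = FALSE)
  fpb <- frames_per_beat(meta$fps, meta$bpm)
  f0 <- if (is.null(meta$start_frame)) min(observations$frame) else
    max(meta$start_frame, min(observations$frame))
  f1 <- if (is.null(meta$end_frame)) max(observations$frame) else
    min(meta$end_frame, max(observations$frame))
  n_beats <- floor((f1 - f0) / fpb) + 1
  target <- f0 + (seq_len(n_beats) - 1) * fpb
  idx <- vapply(target, function(t) which.min(abs(observations$frame - t)),
                integer(1))
  out <- observations[idx, c("frame", "x_px", "y_px", "status")]
  out <- cbind(beat = seq_len(n_beats), out)
  rownames(out) <- NULL
  out
}

#' Snap beat-sampled positions to grid centers, forming a trajectory
#'
#' Converts raw pixel positions to cm via the detection's calibration and
#' associates each to the nearest hexagonal cell center. Positions that fall
#' outside the board are still snapped to the nearest cell but flagged.
#'
#' @param beat_positions Data frame from [sample_beats()].
#' @param detection A `grid_detection_result` (see [detect_grid_centers()]),
#'   or any list with `calibration` and `matched_grid`.
#' @param agent Label, `"prey"` or `"predator"`.
#' @return An object of class `trajectory`: data frame with columns `beat`,
#'   `frame`, `agent`, `x_px`, `y_px`, `q`, `r`, `x_cm`, `y_cm`
#'   (the snapped cell center), `cell`, `status`, `out_of_board`.
#' @export
form_trajectory <- function(beat_positions, detection, agent = "prey") {
  grid <- detection$matched_grid
  cal <- detection$calibration
  if (is.null(grid) || is.null(cal)) {
    stop("detection must carry a matched grid and calibration", call. = FALSE)
  }
  xy_cm <- px_to_cm(cal, cbind(beat_positions$x_px, beat_positions$y_px))
  cells <- nearest_cell(grid, xy_cm)
  oob <- xy_cm[, 1] < grid$spec$origin[1] |
    xy_cm[, 1] > grid$spec$origin[1] + grid$spec$board_width |
    xy_cm[, 2] < grid$spec$origin[2] |
    xy_cm[, 2] > grid$spec$origin[2] + grid$spec$board_height
  out <- data.frame(beat = beat_positions$beat, frame = beat_positions$frame,
                    agent = agent,
                    x_px = beat_positions$x_px, y_px = beat_positions$y_px,
                    q = grid$cells$q[cells], r = grid$cells$r[cells],
                    x_cm = grid$cells$x_cm[cells], y_cm = grid$cells$y_cm[cells],
                    cell = cells, status = beat_positions$status,
                    out_of_board = oob)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Per-beat predator-prey distance series
#'
#' Euclidean distance in cm between the two agents' positions at each beat.
#' By default distances use the snapped cell centers (the grid-association
#' step); set `use_raw = TRUE` to use raw detected positions instead.
#' Trajectories of unequal length are truncated to the common beat range
#' with a warning.
#'
#' @param prey,predator Objects from [form_trajectory()].
#' @param use_raw Use raw pixel-derived cm positions instead of snapped
#'   centers (requires a `calibration` attribute; pass `cal`).
#' @param cal Calibration, required only for `use_raw = TRUE`.
#' @return An object of class `distance_series`: list with `distances_cm`
#'   (per beat), `beats`, and `mean_distance`.
#' @export
distance_series <- function(prey, predator, use_raw = FALSE, cal = NULL) {
  n <- min(nrow(prey), nrow(predator))
  if (n == 0L) stop("zero common beats", call. = FALSE)
  if (nrow(prey) != nrow(predator)) {
    warning(sprintf("truncating to %d common beats", n))
  }
  a <- prey[seq_len(n), ]; b <- predator[seq_len(n), ]
  if (use_raw) {
    if (is.null(cal)) stop("use_raw = TRUE requires 'cal'", call. = FALSE)
    pa <- px_to_cm(cal, cbind(a$x_px, a$y_px))
    pb <- px_to_cm(cal, cbind(b$x_px, b$y_px))
    d <- sqrt(rowSums((pa - pb)^2))
  } else {
    d <- sqrt((a$x_cm - b$x_cm)^2 + (a$y_cm - b$y_cm)^2)
  }
  structure(list(distances_cm = d, beats = a$beat, mean_distance = mean(d)),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series: %d beats, mean %.3f cm\n",
              length(x$distances_cm), x$mean_distance))
  invisible(x)
}

#' Did the prey reach the escape edge?
#'
#' The right side of the board is the escape edge; reaching it at any beat
#' counts as a successful escape.
#'
#' @param prey A [form_trajectory()] result.
#' @param spec The board's [hex_grid_spec()].
#' @return `TRUE` iff any prey cell center lies within one cell width of the
#'   board's right edge.
#' @export
escape_reached <- function(prey, spec) {
  if (nrow(prey) == 0L) stop("empty trajectory", call. = FALSE)
  w <- cell_dimensions(spec$cell_size)[["width"]]
  any(prey$x_cm >= spec$origin[1] + spec$board_width - w)
}

#' Write a trajectory to CSV
#' @param trajectory A [form_trajectory()] result.
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c(
    "beat", "frame", "agent", "x_px", "y_px", "q", "r", "x_cm", "y_cm",
    "status")], path, row.names = FALSE)
  invisible(path)
}

#' Extract both agents' trajectories from frames or a renderer
#'
#' Convenience wrapper for the full pipeline stage: per-frame marker
#' detection ([track_trial()]), beat sampling, and grid snapping.
#'
#' @param frames List of frames or a [trial_renderer()].
#' @param detection A `grid_detection_result` carrying the matched grid and
#'   calibration.
#' @param meta A [trial_video_meta()].
#' @param config A [marker_detector_config()].
#' @return List with `prey` and `predator` trajectories and the per-frame
#'   `observations`.
#' @export
extract_trajectories <- function(frames, detection, meta = trial_video_meta(),
                                 config = marker_detector_config()) {
  obs <- track_trial(frames, config)
  prey_b <- sample_beats(obs[obs$agent == "prey", ], meta)
  pred_b <- sample_beats(obs[obs$agent == "predator", ], meta)
  list(prey = form_trajectory(prey_b, detection, "prey"),
       predator = form_trajectory(pred_b, detection, "predator"),
       observations = obs)
}
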