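# Domain containers.  All pipeline stages operate on these in-memory types;
# file formats are handled exclusively by the io functions.

#' Pose-tracking nose-point series
#'
#' Per-frame nose coordinates in video pixel space (origin top-left, x to the
#' right, y downward), with tracking confidence and frame rate.  Frame indices
#' are 0-based; time is derived as `frame_index / fps`.
#'
#' @param x,y numeric vectors of nose coordinates in pixels.
#' @param fps frames per second (> 0); behavioral videos are typically
#'   recorded at 25 fps (chemogenetic sessions) or 60 fps (photometry
#'   sessions).
#' @param confidence per-frame tracking confidence in `[0, 1]`; defaults to 1.
#' @param frame_index 0-based integer frame indices; defaults to
#'   `0:(n - 1)`.
#' @return an object of class `pose_track` with fields `frame_index`,
#'   `time_s`, `x`, `y`, `confidence`, `fps`.
#' @export
pose_track <- function(x, y, fps, confidence = NULL, frame_index = NULL) {
  n <- length(x)
  if (length(y) != n) stop_fmt("x and y must have equal length")
  if (n < 1) stop_fmt("pose track must contain at least one frame")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop_fmt("fps must be a single positive number")
  if (is.null(confidence)) confidence <- rep(1, n)
  if (length(confidence) != n) stop_fmt("confidence length mismatch")
  if (anyNA(c(x, y))) stop_fmt("coordinates must not contain NA")
  if (any(confidence < 0 | confidence > 1, na.rm = TRUE))
    stop_fmt("confidence must lie in [0, 1]")
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  if (length(frame_index) != n || is.unsorted(frame_index, strictly = TRUE))
    stop_fmt("frame_index must be strictly increasing and match length")
  structure(
    list(frame_index = as.integer(frame_index),
         time_s = frame_index / fps,
         x = as.numeric(x), y = as.numeric(y),
         confidence = as.numeric(confidence),
         fps = fps),
    class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames at %g fps (%.1f s)\n",
              length(x$x), x$fps, length(x$x) / x$fps))
  invisible(x)
}

#' @export
length.pose_track <- function(x) length(x$x)

#' Fiber-photometry signal pair
#'
#' Uniformly sampled calcium-dependent (470 nm excitation) and isosbestic
#' (415 nm) fluorescence channels, with an optional z-scored trace added by
#' [zscore()].
#'
#' @param time_s sample times in seconds (uniform within 1% jitter).
#' @param f470 calcium-dependent channel, arbitrary fluorescence units.
#' @param f415 isosbestic channel, arbitrary fluorescence units.
#' @param fs sampling rate in Hz; estimated from `time_s` when omitted.
#' @param z optional z-scored trace (filled by [zscore()]).
#' @return an object of class `photometry_signal`.
#' @export
photometry_signal <- function(time_s, f470, f415, fs = NULL, z = NULL) {
  n <- length(time_s)
  if (n < 2) stop_fmt("photometry signal needs at least 2 samples")
  if (length(f470) != n || length(f415) != n)
    stop_fmt("channel lengths must match time_s")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_fmt("time_s must be strictly increasing")
  med_dt <- median(dt)
  if (max(abs(dt - med_dt)) > 0.01 * med_dt)
    stop_fmt("non-uniform sampling: jitter exceeds 1%% of the median step")
  if (is.null(fs)) fs <- 1 / med_dt
  if (fs <= 0) stop_fmt("fs must be positive")
  if (!is.null(z) && length(z) != n) stop_fmt("z length mismatch")
  structure(
    list(time_s = as.numeric(time_s), f470 = as.numeric(f470),
         f415 = as.numeric(f415), z = z, fs = fs),
    class = "photometry_signal")
}

#' @export
print.photometry_signal <- function(x, ...) {
  cat(sprintf("<photometry_signal> %d samples at %.6g Hz (%.1f s)%s\n",
              length(x$time_s), x$fs, diff(range(x$time_s)),
              if (is.null(x$z)) "" else ", z-scored"))
  invisible(x)
}

#' Arena geometry and interaction-zone definition
#'
#' Describes the open-field box (50 x 50 cm in the study design), the pencil
#' chambers holding stimuli, and how interaction zones are derived from them:
#' either an annulus from the chamber edge to a margin (3 cm) beyond it, or a
#' disc of fixed pixel radius around the chamber center (100 px for social
#' tests, 50 px for object tests).
#'
#' @param arena_size_px numeric length-2, arena width and height in pixels.
#' @param px_per_cm pixels per centimeter (> 0).
#' @param chambers data.frame with columns `label`, `x`, `y`,
#'   `edge_radius_px` (one row per pencil chamber).
#' @param zone_mode `"radial"` (disc around the chamber center) or
#'   `"annulus"` (chamber edge to `annulus_margin_cm` beyond it).
#' @param annulus_margin_cm annulus width in cm (default 3).
#' @param radial_radius_px disc radius in pixels (default 100; use 50 for
#'   object-recognition sessions).
#' @return an object of class `arena_layout`.
#' @export
arena_layout <- function(arena_size_px, px_per_cm, chambers,
                         zone_mode = c("radial", "annulus"),
                         annulus_margin_cm = 3, radial_radius_px = 100) {
  zone_mode <- match.arg(zone_mode)
  if (length(arena_size_px) != 2 || any(arena_size_px <= 0))
    stop_fmt("arena_size_px must be two positive numbers (width, height)")
  if (px_per_cm <= 0) stop_fmt("px_per_cm must be positive")
  req <- c("label", "x", "y", "edge_radius_px")
  if (!is.data.frame(chambers) || !all(req %in% names(chambers)))
    stop_fmt("chambers must be a data.frame with columns %s",
             paste(req, collapse = ", "))
  if (anyDuplicated(chambers$label)) stop_fmt("chamber labels must be unique")
  if (any(chambers$edge_radius_px <= 0))
    stop_fmt("chamber edge_radius_px must be positive")
  inside <- chambers$x >= 0 & chambers$x <= arena_size_px[1] &
    chambers$y >= 0 & chambers$y <= arena_size_px[2]
  if (!all(inside))
    stop_fmt("chamber center outside arena bounds: %s",
             paste(chambers$label[!inside], collapse = ", "))
  if (annulus_margin_cm <= 0) stop_fmt("annulus_margin_cm must be positive")
  if (radial_radius_px <= 0) stop_fmt("radial_radius_px must be positive")
  structure(
    list(arena_size_px = as.numeric(arena_size_px),
         px_per_cm = px_per_cm,
         chambers = chambers,
         zone_mode = zone_mode,
         annulus_margin_cm = annulus_margin_cm,
         radial_radius_px = radial_radius_px),
    class = "arena_layout")
}

#' @export
print.arena_layout <- function(x, ...) {
  cat(sprintf("<arena_layout> %gx%g px, %g px/cm, %d chambers, mode=%s\n",
              x$arena_size_px[1], x$arena_size_px[2], x$px_per_cm,
              nrow(x$chambers), x$zone_mode))
  invisible(x)
}

#' Session protocol: phase windows and stimulus assignment
#'
#' The recognition-memory protocols are sequences of timed phases
#' (habituation, pretest, sociability or familiarization, discrimination),
#' each presenting stimuli (object, conspecific, novel, familiar) in named
#' chambers.  Sessions in chemogenetic experiments additionally carry a
#' treatment label (saline or CNO) used by the exclusion rule.
#'
#' @param phases data.frame with columns `label`, `start_s`, `end_s`;
#'   windows must be non-overlapping.
#' @param stimuli optional data.frame with columns `phase`, `chamber`,
#'   `stimulus`.
#' @param treatment optional label such as `"saline"` or `"CNO"`.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(phases, stimuli = NULL, treatment = NA_character_) {
  req <- c("label", "start_s", "end_s")
  if (!is.data.frame(phases) || !all(req %in% names(phases)))
    stop_fmt("phases must be a data.frame with columns %s",
             paste(req, collapse = ", "))
  if (any(phases$end_s <= phases$start_s))
    stop_fmt("each phase must have end_s > start_s")
  o <- order(phases$start_s)
  ph <- phases[o, , drop = FALSE]
  if (nrow(ph) > 1 && any(ph$start_s[-1] < ph$end_s[-nrow(ph)]))
    stop_fmt("phase windows must not overlap")
  if (!is.null(stimuli)) {
    reqs <- c("phase", "chamber", "stimulus")
    if (!is.data.frame(stimuli) || !all(reqs %in% names(stimuli)))
      stop_fmt("stimuli must be a data.frame with columns %s",
               paste(reqs, collapse = ", "))
    bad <- setdiff(stimuli$phase, phases$label)
    if (length(bad))
      stop_fmt("stimuli reference unknown phases: %s", paste(bad, collapse = ", "))
  }
  structure(list(phases = phases, stimuli = stimuli, treatment = treatment),
            class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> %d phases (%s)%s\n", nrow(x$phases),
              paste(x$phases$label, collapse = ", "),
              if (is.na(x$treatment)) "" else paste0(", treatment=", x$treatment)))
  invisible(x)
}

#' Spatially binned accumulator over the arena
#'
#' A dense grid of cumulative time (seconds) or event counts.  Rows index y
#' bins, columns index x bins, so a "column" is a constant-x strip of the
#' arena image.  Bins are half-open `[k*bin, (k+1)*bin)`; points on the right
#' or bottom arena edge fall in the last bin.
#'
#' @param grid numeric matrix of nonnegative values.
#' @param bin_px bin size in pixels (default 50, the study's spatial binning).
#' @param origin pixel offset of grid cell (1, 1); default `c(0, 0)`.
#' @param units `"seconds"` or `"counts"`.
#' @return an object of class `heat_map`.
#' @export
heat_map <- function(grid, bin_px = 50, origin = c(0, 0),
                     units = c("seconds", "counts")) {
  units <- match.arg(units)
  if (!is.matrix(grid) || any(grid < 0))
    stop_fmt("grid must be a nonnegative matrix")
  structure(list(grid = grid, bin_px = bin_px, origin = origin, units = units),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> %dx%d bins of %g px, total %.6g %s\n",
              nrow(x$grid), ncol(x$grid), x$bin_px, sum(x$grid), x$units))
  invisible(x)
}

#' Discrete calcium-event train
#'
#' Times (and behavioral frame indices, once aligned) of upward z-score
#' threshold crossings.
#'
#' @param time_s strictly increasing event times in seconds.
#' @param index sample indices of the crossings in the source trace.
#' @param threshold z threshold used for detection.
#' @return an object of class `event_train`.
#' @export
event_train <- function(time_s, index = NULL, threshold = NA_real_) {
  if (length(time_s) > 1 && is.unsorted(time_s, strictly = TRUE))
    stop_fmt("event times must be strictly increasing")
  structure(list(time_s = as.numeric(time_s),
                 index = if (is.null(index)) NULL else as.integer(index),
                 threshold = threshold),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events (threshold z > %g)\n",
              length(x$time_s), x$threshold))
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$time_s)
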