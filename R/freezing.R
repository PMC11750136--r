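# Freezing detection from per-frame changed-pixel fractions (trace fear
# conditioning analysis).

#' Detect freezing bouts
#'
#' A freezing bout is a maximal run of consecutive frames whose
#' changed-pixel fraction is strictly below `threshold` (0.1% by default)
#' lasting strictly more than `min_dur_s` (1 s): a run of exactly
#' `min_dur_s * fps` frames is not a bout.
#'
#' @param pixel_change numeric vector of per-frame changed-pixel fractions
#'   in `[0, 1]`.
#' @param fps frame rate (> 0).
#' @param threshold freezing threshold as a fraction (default 0.001, i.e.
#'   0.1%); comparison is strict.
#' @param min_dur_s minimum bout duration in seconds (default 1); comparison
#'   is strict.
#' @return an object of class `freezing_result`: list with `bouts`
#'   (data.frame `start_s`, `end_s`, `duration_s`), `total_frozen_s`,
#'   `threshold`, `min_dur_s`, `fps`.
#' @export
detect_freezing <- function(pixel_change, fps, threshold = 0.001,
                            min_dur_s = 1) {
  if (fps <= 0) stop_fmt("fps must be positive")
  if (any(pixel_change < 0 | pixel_change > 1))
    stop_fmt("pixel-change values must lie in [0, 1]")
  r <- rle(pixel_change < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_dur_s * fps
  bouts <- data.frame(
    start_s = (starts[keep] - 1L) / fps,
    end_s = ends[keep] / fps)
  bouts$duration_s <- bouts$end_s - bouts$start_s
  structure(list(bouts = bouts, total_frozen_s = sum(bouts$duration_s),
                 threshold = threshold, min_dur_s = min_dur_s, fps = fps),
            class = "freezing_result")
}

#' @export
print.freezing_result <- function(x, ...) {
  cat(sprintf("<freezing_result> %d bout(s), %.2f s frozen (threshold %g, >%g s)\n",
              nrow(x$bouts), x$total_frozen_s, x$threshold, x$min_dur_s))
  invisible(x)
}

#' Percent freezing per protocol phase
#'
#' For each window, 100 times the frozen time overlapping the window divided
#' by the window duration; bouts straddling a window edge contribute only
#' their clipped part.
#'
#' @param result a [detect_freezing()] result.
#' @param windows data.frame with columns `label`, `start_s`, `end_s`.
#' @return named numeric vector of percentages (one per window).
#' @export
percent_freezing <- function(result, windows) {
  req <- c("label", "start_s", "end_s")
  if (!all(req %in% names(windows)))
    stop_fmt("windows must have columns %s", paste(req, collapse = ", "))
  if (any(windows$end_s <= windows$start_s))
    stop_fmt("empty or inverted window")
  b <- result$bouts
  out <- vapply(seq_len(nrow(windows)), function(i) {
    ov <- pmin(b$end_s, windows$end_s[i]) - pmax(b$start_s, windows$start_s[i])
    100 * sum(pmax(ov, 0)) / (windows$end_s[i] - windows$start_s[i])
  }, numeric(1))
  setNames(out, windows$label)
}
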