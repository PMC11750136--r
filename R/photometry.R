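# Photometry conditioning chain: low-pass filter, z-score, downsample to the
# behavioral frame rate, detect threshold-crossing calcium events.

# Zero-phase filtering with odd-reflection padding at both ends, so signals
# with nonzero mean or edge slope are not corrupted by the filter's zero
# initial conditions (signal::filtfilt pads with zeros).  Pad length scales
# with the filter's settling time (longer for lower normalized cutoffs).
filtfilt_pad <- function(bf, x, w_norm) {
  n <- length(x)
  np <- min(n - 1, max(60, ceiling(12 / w_norm)))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(np + 1):(np + n)])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters both channels with an order-`order` Butterworth low-pass applied
#' forward and backward (zero phase, DC gain 1).
#'
#' @param sig a [photometry_signal()].
#' @param cutoff_hz cutoff frequency, Hz (default 40).
#' @param order filter order (default 4).
#' @return the filtered [photometry_signal()].
#' @export
lowpass <- function(sig, cutoff_hz = 40, order = 4) {
  if (sig$fs <= 2 * cutoff_hz)
    stop_fmt("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
             sig$fs, cutoff_hz)
  w <- cutoff_hz / (sig$fs / 2)
  bf <- signal::butter(order, w, type = "low")
  sig$f470 <- filtfilt_pad(bf, sig$f470, w)
  sig$f415 <- filtfilt_pad(bf, sig$f415, w)
  sig
}

#' Optional isosbestic motion correction
#'
#' Least-squares regression of the isosbestic (415 nm) channel onto the
#' calcium-dependent (470 nm) channel, subtracting the fitted motion
#' component.  Off by default in the pipeline: the standard conditioning
#' chain carries both channels without subtraction, but the correction is
#' exposed for recordings with motion artifacts.
#'
#' @param sig a [photometry_signal()].
#' @return the corrected signal (f470 replaced by the regression residual
#'   plus its original mean).
#' @export
isosbestic_correct <- function(sig) {
  fit <- stats::lm.fit(cbind(1, sig$f415), sig$f470)
  sig$f470 <- as.numeric(fit$residuals) + mean(sig$f470)
  sig
}

#' Z-score the calcium-dependent channel
#'
#' `z = (f470 - mean(baseline)) / sd(baseline)`.  The baseline is the whole
#' session by default; a window (in seconds) of at least 10 s may be given
#' for per-phase baselines.
#'
#' @param sig a [photometry_signal()].
#' @param baseline_window optional `c(start_s, end_s)`; default whole trace.
#' @return the signal with the `z` field filled.
#' @export
zscore <- function(sig, baseline_window = NULL) {
  if (is.null(baseline_window))
    baseline_window <- range(sig$time_s)
  if (diff(baseline_window) < 10)
    stop_fmt("baseline window must span at least 10 s")
  sel <- sig$time_s >= baseline_window[1] & sig$time_s <= baseline_window[2]
  mu <- mean(sig$f470[sel])
  s <- sd(sig$f470[sel])
  if (s == 0) stop_fmt("zero baseline variance: cannot z-score a constant signal")
  sig$z <- (sig$f470 - mu) / s
  sig
}

#' Downsample to the behavioral frame rate
#'
#' Anti-alias filters (zero-phase Butterworth at 80% of the target Nyquist)
#' and resamples all channels onto the uniform grid `k / target_hz` aligned
#' to t = 0, with `floor(duration * target_hz) + 1` samples.  Upsampling is
#' refused.
#'
#' @param sig a [photometry_signal()].
#' @param target_hz target rate, Hz (default 60, the behavioral video rate).
#' @return the resampled [photometry_signal()].
#' @export
resample_to <- function(sig, target_hz = 60) {
  if (sig$fs < target_hz)
    stop_fmt("upsampling requested (fs %g < target %g)", sig$fs, target_hz)
  duration <- sig$time_s[length(sig$time_s)]
  t_out <- seq(0, floor(duration * target_hz)) / target_hz
  down <- function(v) {
    if (sig$fs > target_hz) {
      w <- 0.8 * (target_hz / 2) / (sig$fs / 2)
      v <- filtfilt_pad(signal::butter(4, w, type = "low"), v, w)
    }
    approx(sig$time_s, v, xout = t_out, rule = 2)$y
  }
  z <- if (is.null(sig$z)) NULL else down(sig$z)
  photometry_signal(t_out, down(sig$f470), down(sig$f415),
                    fs = target_hz, z = z)
}

#' Detect calcium events as upward threshold crossings
#'
#' One event per upward crossing of the z-score: sample i is an event onset
#' iff `z[i-1] <= threshold < z[i]`.  A suprathreshold excursion therefore
#' counts once regardless of its duration.  The default threshold 2.58 is
#' the two-sided normal quantile at alpha = 0.01.  An optional refractory
#' period suppresses crossings closer than `refractory_s` to the previous
#' accepted event.
#'
#' @param sig a [photometry_signal()] with `z` computed (see [zscore()]), or
#'   a plain numeric z vector (then `fs` is required).
#' @param threshold z threshold (default 2.58).
#' @param refractory_s minimum spacing between events, seconds (default 0).
#' @param fs sampling rate, needed only when `sig` is a plain vector.
#' @return an [event_train()].
#' @export
detect_events <- function(sig, threshold = 2.58, refractory_s = 0, fs = NULL) {
  if (inherits(sig, "photometry_signal")) {
    if (is.null(sig$z)) stop_fmt("z not computed: call zscore() first")
    z <- sig$z
    t <- sig$time_s
  } else {
    if (is.null(fs)) stop_fmt("fs required for a plain z vector")
    z <- as.numeric(sig)
    t <- (seq_along(z) - 1) / fs
  }
  n <- length(z)
  idx <- if (n < 2) integer() else
    1L + which(z[-n] <= threshold & z[-1] > threshold)
  if (refractory_s > 0 && length(idx) > 1) {
    keep <- idx[1]
    for (i in idx[-1]) if (t[i] - t[keep[length(keep)]] >= refractory_s)
      keep <- c(keep, i)
    idx <- keep
  }
  event_train(t[idx], index = idx, threshold = threshold)
}

#' Map events to nose positions
#'
#' Each event is assigned the nose position of the nearest behavioral frame;
#' an event farther than half a frame period from any frame (a clock
#' mismatch, or an event beyond the track) is an error.
#'
#' @param events an [event_train()].
#' @param track a [pose_track()] on the same clock.
#' @return data.frame with `time_s`, `frame` (1-based frame row), `x`, `y`.
#' @export
events_to_positions <- function(events, track) {
  if (length(events) == 0)
    return(data.frame(time_s = numeric(), frame = integer(),
                      x = numeric(), y = numeric()))
  half <- 0.5 / track$fps
  frame <- round(events$time_s * track$fps) + 1L
  bad <- frame < 1L | frame > length(track)
  if (any(bad))
    stop_fmt("event at t=%.3f s lies outside the track", events$time_s[which(bad)[1]])
  dt <- abs(events$time_s - track$time_s[frame])
  if (any(dt > half + 1e-9))
    stop_fmt("clock mismatch: event %.3f s is %.4f s from the nearest frame",
             events$time_s[which.max(dt)], max(dt))
  data.frame(time_s = events$time_s, frame = frame,
             x = track$x[frame], y = track$y[frame])
}
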