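# Session-level orchestration: the standard conditioning chain and a
# synthetic social-discrimination cohort with known ground truth, used to
# validate the in-vivo analyses end to end.

#' Standard two-chamber discrimination layout
#'
#' A 50 x 50 cm open-field arena imaged at `px_per_cm` pixels/cm, with two
#' pencil chambers (labels `"novel"` and `"familiar"`) in opposite corners
#' and radial interaction zones of 100 px, the social-test convention.
#'
#' @param px_per_cm pixel scale (default 10, giving a 500 x 500 px arena).
#' @param zone_mode,radial_radius_px passed to [arena_layout()].
#' @return an [arena_layout()].
#' @export
social_layout <- function(px_per_cm = 10, zone_mode = "radial",
                          radial_radius_px = 100) {
  side <- 50 * px_per_cm
  arena_layout(
    arena_size_px = c(side, side), px_per_cm = px_per_cm,
    chambers = data.frame(label = c("novel", "familiar"),
                          x = c(0.22, 0.78) * side,
                          y = c(0.22, 0.78) * side,
                          edge_radius_px = 4 * px_per_cm),
    zone_mode = zone_mode, radial_radius_px = radial_radius_px)
}

#' Condition a photometry signal for event detection
#'
#' The standard chain: zero-phase Butterworth low-pass at 40 Hz, optional
#' isosbestic motion correction (off by default), z-scoring against the
#' session baseline, and downsampling to the behavioral frame rate (60 Hz).
#'
#' @param sig a raw [photometry_signal()].
#' @param lowpass_hz low-pass cutoff (default 40).
#' @param target_hz output rate (default 60).
#' @param isosbestic apply [isosbestic_correct()] before z-scoring.
#' @param baseline_window optional z-score baseline window, seconds.
#' @return the conditioned [photometry_signal()] with `z` at `target_hz`.
#' @export
condition_signal <- function(sig, lowpass_hz = 40, target_hz = 60,
                             isosbestic = FALSE, baseline_window = NULL) {
  sig <- lowpass(sig, cutoff_hz = lowpass_hz)
  if (isosbestic) sig <- isosbestic_correct(sig)
  sig <- zscore(sig, baseline_window = baseline_window)
  resample_to(sig, target_hz = target_hz)
}

#' Simulate one social-discrimination session with photometry
#'
#' Generates a trajectory attracted to the novel and familiar chambers,
#' couples calcium events to zone occupancy (rate multiplied in the novel
#' zone, emulating novelty-biased activity), runs the full analysis chain
#' (conditioning, event detection at z > 2.58, zone assignment), and
#' returns both ground truth and pipeline outputs.
#'
#' @param seed RNG seed for the session.
#' @param layout an [arena_layout()]; default [social_layout()].
#' @param duration_s session length, seconds (default 600).
#' @param fps behavioral frame rate (default 60).
#' @param gain_novel,gain_familiar chamber attraction gains (the subject's
#'   behavioral preference; defaults 1.2 / 0.8 favor the novel chamber).
#' @param baseline_rate baseline calcium-event rate, events/s (default 0.1).
#' @param multiplier_novel event-rate multiplier inside the novel zone
#'   (default 3).
#' @param fs photometry sampling rate before downsampling (default 120).
#' @param threshold event-detection z threshold (default 2.58).
#' @param refractory_s detection refractory period, seconds (default 1.5):
#'   suppresses repeat crossings while a transient's decay rides the
#'   threshold, so one transient is counted once.
#' @return a list: `track`, `occupancy`, `signal` (conditioned),
#'   `events` (detected [event_train()]), `positions` (event positions),
#'   `true_event_times`, `discrimination_index`, `event_ratio` (detected
#'   novel/familiar zone event ratio), `true_rate_ratio` (ground-truth
#'   per-second event-rate ratio novel vs familiar zone), `zone_summary`
#'   (per-zone seconds and true/detected event counts).
#' @export
simulate_recognition_session <- function(seed, layout = social_layout(),
                                         duration_s = 600, fps = 60,
                                         gain_novel = 1.2, gain_familiar = 0.8,
                                         baseline_rate = 0.1,
                                         multiplier_novel = 3, fs = 120,
                                         threshold = 2.58, refractory_s = 1.5) {
  tm <- trajectory_model(attraction = c(novel = gain_novel,
                                        familiar = gain_familiar))
  track <- simulate_trajectory(tm, layout, duration_s, fps = fps,
                               seed = substream_seed(seed, 0))
  cm <- coupling_model(baseline_rate = baseline_rate,
                       multipliers = c(novel = multiplier_novel))
  sim <- simulate_photometry(track, layout, cm, fs = fs,
                             seed = substream_seed(seed, 1))
  occ <- assign_zones(track, layout)
  sig <- condition_signal(sim$signal, target_hz = fps)
  ev <- detect_events(sig, threshold = threshold, refractory_s = refractory_s)
  # the resampled grid extends half a frame past the last video frame; a
  # crossing there has no behavioral frame and is dropped
  keep <- ev$time_s <= (length(track) - 0.5) / fps
  ev <- event_train(ev$time_s[keep], ev$index[keep], ev$threshold)
  pos <- events_to_positions(ev, track)
  di <- discrimination_index(occ$times[["novel"]], occ$times[["familiar"]])
  ratio <- zone_event_ratio(pos$frame, occ, "novel", "familiar")
  true_frames <- pmin(length(track), round(sim$true_event_times * fps) + 1L)
  tz <- occ$zone[true_frames]
  dz <- occ$zone[pos$frame]
  t_n <- occ$times[["novel"]]; t_f <- occ$times[["familiar"]]
  true_rate_ratio <- if (t_n > 0 && t_f > 0 && sum(tz == "familiar") > 0)
    (sum(tz == "novel") / t_n) / (sum(tz == "familiar") / t_f) else NA_real_
  zone_summary <- data.frame(
    zone = c("novel", "familiar"),
    seconds = c(t_n, t_f),
    n_true = c(sum(tz == "novel"), sum(tz == "familiar")),
    n_detected = c(sum(dz == "novel"), sum(dz == "familiar")))
  list(track = track, occupancy = occ, signal = sig, events = ev,
       positions = pos, true_event_times = sim$true_event_times,
       discrimination_index = di, event_ratio = ratio,
       true_rate_ratio = true_rate_ratio, zone_summary = zone_summary)
}

#' Simulate a social-discrimination cohort
#'
#' `n_subjects` sessions whose novel-chamber attraction gains are spread
#' over `gain_range` (subjects differ in novelty preference, so the cohort
#' spans a range of discrimination indices), all sharing the same
#' location-coupled calcium model.  Per-subject seeds are substreams of
#' `seed`.
#'
#' @param seed cohort RNG seed.
#' @param n_subjects cohort size (default 8).
#' @param gain_range range of novel-chamber attraction gains (default
#'   `c(0.8, 1.6)`, spanning discrimination indices of roughly 0.5 to 0.9).
#' @param ... further arguments to [simulate_recognition_session()].
#' @return data.frame with one row per subject: `subject`,
#'   `discrimination_index`, `event_ratio`, `true_rate_ratio`, `n_events`,
#'   `t_novel`, `t_familiar`, `n_true_novel`, `n_true_familiar`,
#'   `n_det_novel`, `n_det_familiar`.  The attribute `pooled_rate_ratio`
#'   gives the cohort-pooled ground-truth event-rate ratio
#'   (novel vs familiar zone), the estimator of the programmed coupling
#'   multiplier.
#' @export
simulate_recognition_cohort <- function(seed, n_subjects = 8,
                                        gain_range = c(0.8, 1.6), ...) {
  gains <- seq(gain_range[1], gain_range[2], length.out = n_subjects)
  rows <- lapply(seq_len(n_subjects), function(i) {
    s <- simulate_recognition_session(seed = substream_seed(seed, i),
                                      gain_novel = gains[i], ...)
    zs <- s$zone_summary
    data.frame(subject = i,
               discrimination_index = s$discrimination_index,
               event_ratio = s$event_ratio,
               true_rate_ratio = s$true_rate_ratio,
               n_events = length(s$events),
               t_novel = zs$seconds[1], t_familiar = zs$seconds[2],
               n_true_novel = zs$n_true[1], n_true_familiar = zs$n_true[2],
               n_det_novel = zs$n_detected[1], n_det_familiar = zs$n_detected[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "pooled_rate_ratio") <-
    (sum(out$n_true_novel) / sum(out$t_novel)) /
    (sum(out$n_true_familiar) / sum(out$t_familiar))
  out
}
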