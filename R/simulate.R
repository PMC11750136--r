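# Synthetic-data generators with known ground truth.  Each generator is a
# pure function of (parameters, seed): reruns are bit-identical, and the
# caller's RNG state is never disturbed.

#' Trajectory model for the biased random walk
#'
#' The simulated mouse alternates between free diffusion and an "attracted"
#' state in which its step acquires a drift toward one chamber.  Attraction
#' gains set both how often a chamber captures the walk and how strong the
#' drift is, so expected zone occupancy grows with a chamber's gain.
#'
#' @param step_sd_px per-frame step standard deviation, pixels (> 0).
#' @param attraction named numeric vector of per-chamber drift gains
#'   (>= 0), names matching layout chamber labels; chambers without an entry
#'   get gain 0.
#' @param persistence probability of keeping the current behavioral state on
#'   each frame, in `[0, 1)`; dwell times are geometric with mean
#'   `1 / (1 - persistence)` frames.
#' @param seed default seed used by [simulate_trajectory()].
#' @return an object of class `trajectory_model`.
#' @export
trajectory_model <- function(step_sd_px = 2.5, attraction = numeric(),
                             persistence = 0.99, seed = NULL) {
  stopifnot(step_sd_px > 0, all(attraction >= 0),
            persistence >= 0, persistence < 1)
  if (length(attraction) && is.null(names(attraction)))
    stop_fmt("attraction gains must be named by chamber label")
  structure(list(step_sd_px = step_sd_px, attraction = attraction,
                 persistence = persistence, seed = seed),
            class = "trajectory_model")
}

#' Simulate an exploration trajectory
#'
#' Bounded reflecting random walk over the arena with state-switching drift
#' toward attracted chambers (see [trajectory_model()]).  The walk starts at
#' the arena center.
#'
#' @param model a [trajectory_model()].
#' @param layout an [arena_layout()].
#' @param duration_s session duration, seconds (> 0).
#' @param fps frame rate (default 60, the photometry-session video rate).
#' @param seed RNG seed; defaults to `model$seed`.
#' @return a [pose_track()]; the attribute `state` records the per-frame
#'   behavioral state (0 = free, k = attracted to chamber k).
#' @export
simulate_trajectory <- function(model, layout, duration_s, fps = 60,
                                seed = model$seed) {
  if (!inherits(model, "trajectory_model")) stop_fmt("model must be a trajectory_model")
  if (duration_s <= 0) stop_fmt("duration_s must be positive")
  labels <- layout$chambers$label
  bad <- setdiff(names(model$attraction), labels)
  if (length(bad))
    stop_fmt("attraction names not in layout: %s", paste(bad, collapse = ", "))
  gain <- setNames(rep(0, length(labels)), labels)
  gain[names(model$attraction)] <- model$attraction
  n <- floor(duration_s * fps)
  res <- with_seed(seed, .walk_cpp(
    n, layout$arena_size_px[1] / 2, layout$arena_size_px[2] / 2,
    layout$arena_size_px[1], layout$arena_size_px[2],
    model$step_sd_px, layout$chambers$x, layout$chambers$y,
    as.numeric(gain), model$persistence))
  tr <- pose_track(res$x, res$y, fps = fps)
  attr(tr, "state") <- res$state
  tr
}

#' Location-coupled calcium-transient model
#'
#' Calcium events arise as an inhomogeneous Poisson process whose rate is the
#' baseline rate times a per-zone multiplier.  Each event adds a
#' double-exponential transient (difference of exponentials, peak-normalized
#' to `amplitude`); defaults of 0.05 s rise and 1 s decay resemble a slow
#' calcium sensor.  Gaussian noise of unit standard deviation is added to the
#' calcium-dependent channel, so `amplitude` is the approximate peak z of a
#' transient; the isosbestic channel carries noise only.
#'
#' @param baseline_rate events/s at multiplier 1 (>= 0).
#' @param multipliers named numeric vector of per-zone rate multipliers
#'   (>= 0), names matching chamber labels plus optionally `"none"` for
#'   outside all zones; unlisted zones default to 1.
#' @param amplitude transient peak, z units.
#' @param tau_rise,tau_decay kernel time constants, seconds
#'   (`tau_decay > tau_rise > 0`).
#' @param noise_sd channel noise standard deviation.
#' @param seed default seed used by [simulate_photometry()].
#' @return an object of class `coupling_model`.
#' @export
coupling_model <- function(baseline_rate = 0.3, multipliers = numeric(),
                           amplitude = 4, tau_rise = 0.05, tau_decay = 1,
                           noise_sd = 1, seed = NULL) {
  stopifnot(baseline_rate >= 0, all(multipliers >= 0),
            tau_rise > 0, tau_decay > tau_rise, noise_sd >= 0)
  if (length(multipliers) && is.null(names(multipliers)))
    stop_fmt("multipliers must be named by zone label")
  structure(list(baseline_rate = baseline_rate, multipliers = multipliers,
                 amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, noise_sd = noise_sd, seed = seed),
            class = "coupling_model")
}

#' Simulate a photometry recording coupled to a trajectory
#'
#' Event times are drawn frame-by-frame at the behavioral rate with
#' probability `rate(zone at t) / fps` (a thinned Poisson process; rates must
#' satisfy `rate < fps`).  The calcium-dependent channel is the superposition
#' of transient kernels plus Gaussian noise; the isosbestic channel is noise
#' only.  Ground-truth event times are returned for validation.
#'
#' @param track a [pose_track()] covering the session.
#' @param layout an [arena_layout()] defining the zones.
#' @param model a [coupling_model()].
#' @param fs photometry sampling rate, Hz (default 120).
#' @param seed RNG seed; defaults to `model$seed`.
#' @return a list with `signal` (a [photometry_signal()]) and
#'   `true_event_times` (seconds, strictly increasing).
#' @export
simulate_photometry <- function(track, layout, model, fs = 120,
                                seed = model$seed) {
  if (!inherits(model, "coupling_model")) stop_fmt("model must be a coupling_model")
  if (fs < 2 / model$tau_rise)
    warning("fs below 2/tau_rise: transient rise undersampled")
  occ <- assign_zones(track, layout)
  mult <- setNames(rep(1, nrow(layout$chambers) + 1),
                   c(layout$chambers$label, "none"))
  mult[names(model$multipliers)] <- model$multipliers
  rate <- model$baseline_rate * as.numeric(mult[occ$zone])
  if (any(rate >= track$fps))
    stop_fmt("event rate must stay below the behavioral frame rate")
  duration <- length(track) / track$fps
  n <- floor(duration * fs) + 1L
  t_grid <- (seq_len(n) - 1L) / fs
  out <- with_seed(seed, {
    hit <- runif(length(rate)) < rate / track$fps
    ev <- track$time_s[hit]
    x <- numeric(n)
    si <- pmin(n, round(ev * fs) + 1L)
    for (i in si) x[i] <- x[i] + 1
    a_d <- exp(-1 / (fs * model$tau_decay))
    a_r <- exp(-1 / (fs * model$tau_rise))
    m <- 0:ceiling(10 * model$tau_decay * fs)
    norm <- max(a_d^m - a_r^m)
    pulse <- as.numeric(stats::filter(x, a_d, method = "recursive") -
                        stats::filter(x, a_r, method = "recursive"))
    f470 <- model$amplitude / norm * pulse + rnorm(n, sd = model$noise_sd)
    f415 <- rnorm(n, sd = model$noise_sd)
    list(ev = ev, f470 = f470, f415 = f415)
  })
  list(signal = photometry_signal(t_grid, out$f470, out$f415, fs = fs),
       true_event_times = out$ev)
}

#' Simulate a per-frame pixel-change fraction series
#'
#' Emulates the motion statistic underlying freezing detection: outside
#' freezing bouts the changed-pixel fraction fluctuates around
#' `moving_level`, inside bouts around `frozen_level`; values are clipped to
#' `[0, 1]`.
#'
#' @param bouts data.frame or list of `(start_s, end_s)` freezing bouts;
#'   must not overlap.
#' @param duration_s total duration, seconds.
#' @param fps frame rate (default 25, the conditioning-video rate).
#' @param moving_level,frozen_level mean changed-pixel fraction outside /
#'   inside bouts; the defaults straddle the 0.1% freezing threshold.
#' @param noise_sd Gaussian noise SD of the series.
#' @param seed RNG seed.
#' @return numeric vector of per-frame fractions (length
#'   `floor(duration_s * fps)`).
#' @export
simulate_pixelchange <- function(bouts, duration_s, fps = 25,
                                 moving_level = 0.02, frozen_level = 5e-4,
                                 noise_sd = 1e-4, seed = NULL) {
  stopifnot(frozen_level < 0.001, moving_level > 0.001, duration_s > 0)
  b <- as.data.frame(bouts)
  if (nrow(b)) {
    names(b)[1:2] <- c("start_s", "end_s")
    if (any(b$end_s <= b$start_s)) stop_fmt("each bout needs end_s > start_s")
    if (any(b$start_s < 0) || any(b$end_s > duration_s))
      stop_fmt("bouts must lie within [0, duration_s]")
    o <- order(b$start_s)
    if (nrow(b) > 1 && any(b$start_s[o][-1] < b$end_s[o][-nrow(b)]))
      stop_fmt("bouts must not overlap")
  }
  n <- floor(duration_s * fps)
  t0 <- (seq_len(n) - 1L) / fps
  frozen <- rep(FALSE, n)
  for (i in seq_len(nrow(b)))
    frozen <- frozen | (t0 >= b$start_s[i] & t0 < b$end_s[i])
  with_seed(seed, {
    v <- ifelse(frozen, frozen_level, moving_level) + rnorm(n, sd = noise_sd)
    pmin(pmax(v, 0), 1)
  })
}

#' Simulate a region-by-subject presynaptic cell-count table
#'
#' Negative-binomial counts around per-region means, matching the
#' overdispersion of tracing cell counts across brains.
#'
#' @param region_means named numeric vector of expected counts per region
#'   (> 0).
#' @param dispersion negative-binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param n_subjects number of subjects (columns).
#' @param seed RNG seed.
#' @return integer matrix (region x subject) with dimnames.
#' @export
simulate_cellcounts <- function(region_means, dispersion = 10, n_subjects = 5,
                                seed = NULL) {
  stopifnot(all(region_means > 0), n_subjects >= 1, dispersion > 0)
  if (is.null(names(region_means)))
    names(region_means) <- paste0("region_", seq_along(region_means))
  with_seed(seed, {
    draw <- function(mu) {
      if (is.infinite(dispersion)) rpois(n_subjects, mu)
      else rnbinom(n_subjects, size = dispersion, mu = mu)
    }
    m <- t(vapply(region_means, draw, numeric(n_subjects)))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(names(region_means), paste0("subject_", seq_len(n_subjects)))
    m
  })
}

#' Simulate photo-evoked current sweeps
#'
#' Each sweep is Gaussian baseline noise plus, when `peak_pA` is nonzero, an
#' exponential-decay response beginning at `onset_s` (instantaneous rise).
#' Averaging sweeps converges to the template.
#'
#' @param n_sweeps number of repetitions (3-6 in typical protocols).
#' @param baseline_sd_pA noise standard deviation, pA.
#' @param response list with `onset_s`, `peak_pA` (signed: negative for an
#'   inward EPSC at -70 mV, positive for an outward IPSC at +12 mV) and
#'   `tau_decay_s`.
#' @param duration_s sweep length, seconds.
#' @param fs sampling rate, Hz (default 10000).
#' @param seed RNG seed.
#' @return a [sweep_set()]; attribute `template` holds the noise-free
#'   response trace.
#' @export
simulate_ephys_sweeps <- function(n_sweeps = 6, baseline_sd_pA = 5,
                                  response = list(onset_s = 0.1, peak_pA = -80,
                                                  tau_decay_s = 0.02),
                                  duration_s = 0.3, fs = 10000, seed = NULL) {
  stopifnot(fs > 0, n_sweeps >= 1, duration_s > response$onset_s)
  n <- floor(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  template <- numeric(n)
  post <- t >= response$onset_s
  template[post] <- response$peak_pA *
    exp(-(t[post] - response$onset_s) / response$tau_decay_s)
  sweeps <- with_seed(seed,
    template + matrix(rnorm(n * n_sweeps, sd = baseline_sd_pA), n, n_sweeps))
  ss <- sweep_set(t, sweeps, stim_onset_s = response$onset_s)
  attr(ss, "template") <- template
  ss
}
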