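test_that("the low-pass filter has DC gain 1 and attenuates above cutoff", {
  n <- 2400; fs <- 240
  t <- (0:(n - 1)) / fs
  const <- photometry_signal(t, rep(7, n), rep(3, n), fs = fs)
  lf <- lowpass(const, 40)
  expect_equal(lf$f470, rep(7, n), tolerance = 1e-6)
  # 60 Hz sinusoid above the 40 Hz cutoff: amplitude must drop below 50%
  s60 <- photometry_signal(t, sin(2 * pi * 60 * t), rep(0, n), fs = fs)
  out <- lowpass(s60, 40)
  mid <- out$f470[800:1600]
  expect_lt(max(abs(mid)), 0.5)
  # and a 5 Hz passband tone is preserved
  s5 <- photometry_signal(t, sin(2 * pi * 5 * t), rep(0, n), fs = fs)
  expect_gt(max(abs(lowpass(s5, 40)$f470[800:1600])), 0.99)
  s_low <- photometry_signal((0:599) / 60, rnorm(600), rnorm(600), fs = 60)
  expect_error(lowpass(s_low, 40), "twice the cutoff")
})

test_that("z-scoring standardizes against the baseline window", {
  n <- 3000; fs <- 100
  t <- (0:(n - 1)) / fs
  f <- withr::with_seed(5, rnorm(n, mean = 5, sd = 2))
  sig <- zscore(photometry_signal(t, f, rep(0, n), fs = fs))
  expect_lt(abs(mean(sig$z)), 1e-9)
  expect_lt(abs(sd(sig$z) - 1), 1e-9)
  expect_error(zscore(photometry_signal(t, rep(4, n), rep(0, n), fs = fs)),
               "variance")
  # a noise-free transient of 4 baseline SDs peaks at z ~= 4 when z-scored
  # against the quiet baseline window
  f2 <- c(withr::with_seed(6, rnorm(1500, 10, 0.5)), rep(10, 1500))
  f2[2000] <- 10 + 4 * 0.5
  sig2 <- zscore(photometry_signal(t, f2, rep(0, n), fs = fs),
                 baseline_window = c(0, 14.99))
  expect_lt(abs(max(sig2$z) - 4), 0.3)
  expect_error(zscore(photometry_signal(t, f, rep(0, n)),
                      baseline_window = c(0, 5)), "10 s")
})

test_that("resampling lands on the target grid and preserves the passband", {
  fs <- 120; n <- 1200
  t <- (0:(n - 1)) / fs
  sig <- photometry_signal(t, 3 + sin(2 * pi * t), rep(1, n), fs = fs)
  out <- resample_to(sig, 60)
  expect_equal(out$time_s, seq(0, floor(t[n] * 60)) / 60)
  expect_equal(out$fs, 60)
  expect_equal(resample_to(photometry_signal(t, rep(2, n), rep(0, n)), 60)$f470,
               rep(2, 600), tolerance = 1e-6)
  # 1 Hz amplitude preserved within 1%
  mid <- out$f470[100:500]
  expect_lt(abs((max(mid) - min(mid)) / 2 - 1), 0.01)
  expect_error(resample_to(photometry_signal((0:99) / 30, rnorm(100),
                                             rnorm(100)), 60),
               "upsampling")
})

test_that("event detection counts one rising edge per excursion", {
  expect_length(detect_events(c(0, 1, 2, 1, 0), fs = 10)$time_s, 0)
  # a long boxcar above threshold is a single event at its onset
  z <- c(rep(0, 10), rep(5, 200), rep(0, 10))
  ev <- detect_events(z, fs = 10)
  expect_length(ev$time_s, 1)
  expect_equal(ev$time_s, 1.0)
  # seven separated excursions
  z7 <- rep(0, 700)
  for (k in 1:7) z7[(k * 90):(k * 90 + 5)] <- 3
  expect_length(detect_events(z7, fs = 10)$time_s, 7)
})

naive_event_scan <- function(z, threshold) {
  hits <- integer()
  for (i in 2:length(z))
    if (z[i - 1] <= threshold && z[i] > threshold) hits <- c(hits, i)
  hits
}

test_that("event detection matches an exhaustive reference scan on random traces", {
  for (seed in 1:100) {
    z <- withr::with_seed(seed, as.numeric(arima.sim(list(ar = 0.9), 400)))
    ev <- detect_events(z, threshold = 1.5, fs = 60)
    expect_identical(ev$index, naive_event_scan(z, 1.5))
  }
})

test_that("the refractory period suppresses rapid re-crossings", {
  z <- rep(0, 100)
  z[c(10, 20, 80)] <- 3   # crossings at samples 10, 20, 80 (fs = 10)
  expect_length(detect_events(z, fs = 10)$time_s, 3)
  ev <- detect_events(z, fs = 10, refractory_s = 2)
  expect_equal(ev$index, c(10L, 80L))
})

test_that("event counts are invariant to amplitude rescaling before z-scoring", {
  n <- 6000; fs <- 100
  t <- (0:(n - 1)) / fs
  f <- withr::with_seed(11, rnorm(n, 5, 0.4))
  f[seq(500, 5500, by = 500)] <- f[seq(500, 5500, by = 500)] + 4
  count_for <- function(scale) {
    sig <- zscore(photometry_signal(t, scale * f, rep(0, n), fs = fs))
    length(detect_events(sig)$time_s)
  }
  expect_equal(count_for(1), count_for(7.3))
  expect_equal(count_for(1), count_for(0.02))
})

test_that("filtering and downsampling commute for band-limited input", {
  fs <- 240; n <- 4800
  t <- (0:(n - 1)) / fs
  f <- 2 + sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 8 * t)
  sig <- photometry_signal(t, f, rep(0, n), fs = fs)
  a <- resample_to(lowpass(sig, 40), 60)$f470
  b <- lowpass(resample_to(sig, 120), 40)
  b <- resample_to(b, 60)$f470
  keep <- 60:(length(a) - 60)   # ignore filter edge transients
  rms <- sqrt(mean((a[keep] - b[keep])^2)) / sqrt(mean(a[keep]^2))
  expect_lt(rms, 0.01)
})

test_that("events map to the nose position of the nearest frame", {
  tr <- pose_track(seq(0, 120, length.out = 121), rep(2, 121), fps = 60)
  ev <- event_train(c(0.5, 1.0), threshold = 2.58)
  pos <- events_to_positions(ev, tr)
  expect_equal(pos$frame, c(31, 61))
  expect_equal(pos$x[2], tr$x[61])
  # an event beyond the track end has no frame
  expect_error(events_to_positions(event_train(5), tr), "outside the track")
})

test_that("detected events align with ground-truth transient onsets at sparse rates", {
  lay <- social_layout()
  d_all <- c()
  for (k in 1:4) {
    tr <- simulate_trajectory(trajectory_model(), lay, 600, fps = 60,
                              seed = 500 + k)
    sim <- simulate_photometry(tr, lay, coupling_model(baseline_rate = 0.05),
                               seed = 600 + k)
    ev <- detect_events(condition_signal(sim$signal), refractory_s = 1.5)
    d_all <- c(d_all, vapply(ev$time_s,
                             function(t) min(abs(t - sim$true_event_times)),
                             numeric(1)))
  }
  # threshold crossings lag onsets by the transient rise (~0.1 s); 0.25 s
  # covers rise plus filter scale
  expect_gt(mean(d_all <= 0.25), 0.85)
})
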