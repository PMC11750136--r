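test_that("generators are pure functions of parameters and seed", {
  lay <- tiny_layout()
  tm <- trajectory_model(attraction = c(A = 1), seed = 7)
  t1 <- simulate_trajectory(tm, lay, 10, fps = 25)
  t2 <- simulate_trajectory(tm, lay, 10, fps = 25)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  # caller RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_trajectory(tm, lay, 2, fps = 25))
  expect_identical(.Random.seed, before)
  cc <- simulate_cellcounts(c(EN = 250, BLA = 120), seed = 3)
  expect_identical(cc, simulate_cellcounts(c(EN = 250, BLA = 120), seed = 3))
  ss <- simulate_ephys_sweeps(seed = 9)
  expect_identical(ss$sweeps, simulate_ephys_sweeps(seed = 9)$sweeps)
})

test_that("trajectories stay in bounds and need a positive duration", {
  lay <- tiny_layout()
  tr <- simulate_trajectory(trajectory_model(step_sd_px = 15), lay, 60,
                            fps = 60, seed = 2)
  expect_true(all(tr$x >= 0 & tr$x <= 200))
  expect_true(all(tr$y >= 0 & tr$y <= 200))
  expect_error(simulate_trajectory(trajectory_model(), lay, 0, seed = 1),
               "duration")
})

test_that("unbiased walks occupy zones in proportion to area", {
  lay <- tiny_layout()
  # fast-mixing walk, no attraction: stationary distribution is uniform, so
  # expected zone occupancy is the zone's area fraction.  The sampling SD
  # uses an effective sample size n / tau, with tau the integrated
  # autocorrelation time of the x coordinate.
  tm <- trajectory_model(step_sd_px = 20, persistence = 0)
  tr <- simulate_trajectory(tm, lay, 10000 / 60, fps = 60, seed = 42)
  occ <- assign_zones(tr, lay)
  p_zone <- pi * 50^2 / (200 * 200)  # disc fully inside the arena
  ac <- acf(tr$x, lag.max = 200, plot = FALSE)$acf[-1]
  tau <- 1 + 2 * sum(ac[seq_len(max(1, which(ac < 0)[1] - 1))])
  n_eff <- length(tr) / tau
  se <- sqrt(p_zone * (1 - p_zone) / n_eff)
  for (z in c("A", "B")) {
    p_hat <- occ$times[[z]] / (length(tr) / tr$fps)
    expect_lt(abs(p_hat - p_zone), 3 * se)
  }
})

test_that("doubling a chamber's attraction gain biases the discrimination index above chance", {
  lay <- social_layout()
  di <- vapply(1:20, function(i) {
    tm <- trajectory_model(attraction = c(novel = 1.6, familiar = 0.8))
    tr <- simulate_trajectory(tm, lay, 300, fps = 60, seed = 9000 + i)
    occ <- assign_zones(tr, lay)
    discrimination_index(occ$times[["novel"]], occ$times[["familiar"]])
  }, numeric(1))
  expect_gt(mean(di), 0.5)
})

test_that("photometry event counts follow the programmed Poisson rate", {
  lay <- tiny_layout()
  tr <- simulate_trajectory(trajectory_model(), lay, 300, fps = 60, seed = 1)
  cm0 <- coupling_model(baseline_rate = 0)
  sim0 <- simulate_photometry(tr, lay, cm0, seed = 5)
  expect_length(sim0$true_event_times, 0)
  # with no events the calcium channel is pure noise: unit SD, zero mean
  expect_lt(abs(mean(sim0$signal$f470)), 0.05)
  expect_lt(abs(sd(sim0$signal$f470) - 1), 0.05)

  cm <- coupling_model(baseline_rate = 0.2)
  counts <- vapply(1:50, function(i)
    length(simulate_photometry(tr, lay, cm, seed = 100 + i)$true_event_times),
    numeric(1))
  expect_lt(abs(mean(counts) - 60), 2 * sqrt(60))
  # ground-truth times are strictly increasing and inside the session
  sim <- simulate_photometry(tr, lay, cm, seed = 101)
  expect_false(is.unsorted(sim$true_event_times, strictly = TRUE))
  expect_true(all(sim$true_event_times >= 0 &
                  sim$true_event_times <= length(tr) / tr$fps))
})

test_that("a programmed zone multiplier appears in the ground-truth event rates", {
  lay <- social_layout()
  rr <- vapply(1:5, function(i) {
    s <- simulate_recognition_session(seed = 7000 + i)
    s$true_rate_ratio
  }, numeric(1))
  expect_lt(abs(median(rr) - 3) / 3, 0.25)
})

test_that("pixel-change series realize programmed freezing bouts", {
  s <- simulate_pixelchange(data.frame(start_s = 10, end_s = 15),
                            duration_s = 30, fps = 25, noise_sd = 0, seed = 1)
  fr <- detect_freezing(s, fps = 25)
  expect_equal(fr$bouts$start_s, 10)
  expect_equal(fr$bouts$end_s, 15)
  s0 <- simulate_pixelchange(data.frame(start_s = numeric(), end_s = numeric()),
                             duration_s = 300, fps = 25, seed = 2)
  expect_equal(detect_freezing(s0, fps = 25)$total_frozen_s, 0)
  # bouts totalling 30 s of 300 s with small noise: ~10% freezing
  b <- data.frame(start_s = c(50, 200), end_s = c(70, 210))
  s2 <- simulate_pixelchange(b, duration_s = 300, fps = 25, seed = 3)
  fr2 <- detect_freezing(s2, fps = 25)
  pct <- percent_freezing(fr2, data.frame(label = "all", start_s = 0, end_s = 300))
  expect_lt(abs(pct[["all"]] - 10), 1)
  expect_error(
    simulate_pixelchange(data.frame(start_s = c(1, 3), end_s = c(5, 6)),
                         duration_s = 10, seed = 1),
    "overlap")
})

test_that("cell-count tables approach the Poisson limit at large dispersion", {
  cc <- simulate_cellcounts(c(EN = 250, BLA = 250, SP = 250, SPm = 250),
                            dispersion = Inf, n_subjects = 40, seed = 11)
  expect_equal(dim(cc), c(4, 40))
  for (r in 1:4)
    expect_lt(abs(mean(cc[r, ]) - 250), 3 * sqrt(250 / 40))
  shaped <- simulate_cellcounts(c(a = 100, b = 50, c = 20, d = 10),
                                n_subjects = 5, seed = 4)
  expect_equal(dim(shaped), c(4, 5))
})

test_that("simulated sweeps embed the programmed response", {
  null <- simulate_ephys_sweeps(response = list(onset_s = 0.1, peak_pA = 0,
                                                tau_decay_s = 0.02),
                                seed = 21)
  avg <- average_trace(null)
  m0 <- classify_response(avg, null$time, onset = 0.1, stat = "mean")
  expect_false(m0$is_response)
  expect_equal(m0$peak_amplitude_pa, 0)
  big <- simulate_ephys_sweeps(baseline_sd_pA = 5,
                               response = list(onset_s = 0.1, peak_pA = -50,
                                               tau_decay_s = 0.02),
                               seed = 22)
  m1 <- classify_response(average_trace(big), big$time, onset = 0.1)
  expect_true(m1$is_response)
})
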