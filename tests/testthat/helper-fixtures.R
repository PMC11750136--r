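# Fixtures built in code: small files and standard objects shared by tests.

# Write a three-header-row pose CSV (scorer / bodyparts / coords) and return
# its path.
write_pose_csv <- function(x, y, likelihood = rep(1, length(x)),
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pose.csv")
  lines <- c(
    "scorer,model,model,model",
    "bodyparts,nose,nose,nose",
    "coords,x,y,likelihood",
    sprintf("%d,%s,%s,%s", seq_along(x) - 1L, format(x), format(y),
            format(likelihood)))
  writeLines(lines, path)
  path
}

write_photometry_csv <- function(time_s, f470, f415,
                                 dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "phot.csv")
  write.csv(data.frame(time_s = time_s, f470 = f470, f415 = f415), path,
            row.names = FALSE)
  path
}

# A small two-chamber layout in a 200 x 200 px arena, radial zones of 50 px.
tiny_layout <- function(zone_mode = "radial") {
  arena_layout(
    arena_size_px = c(200, 200), px_per_cm = 4,
    chambers = data.frame(label = c("A", "B"), x = c(50, 150), y = c(50, 150),
                          edge_radius_px = 20),
    zone_mode = zone_mode, annulus_margin_cm = 3, radial_radius_px = 50)
}

# A photometry signal whose z-scored trace contains transients of the given
# peak amplitudes (in baseline-noise SDs) at the given times.
signal_with_transients <- function(times, amps, duration = 60, fs = 200,
                                   noise_sd = 0.05, seed = 1) {
  n <- floor(duration * fs) + 1
  t <- (seq_len(n) - 1) / fs
  f <- withr::with_seed(seed, rnorm(n, mean = 5, sd = noise_sd))
  for (i in seq_along(times)) {
    post <- t >= times[i]
    f[post] <- f[post] + amps[i] * noise_sd *
      exp(-(t[post] - times[i]) / 0.5)
  }
  photometry_signal(t, f, rep(0, n), fs = fs)
}

# Path to the shipped presynaptic cell-count fixture.
counts_fixture_path <- function() {
  system.file("extdata", "presynaptic_counts.csv", package = "recogmem",
              mustWork = TRUE)
}
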