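# File ingestion and result serialization.  All validation happens here so
# downstream modules can assume well-formed domain objects.

#' Read a pose-estimation table (three-header-row CSV dialect)
#'
#' Parses the tracker export dialect whose first three rows are `scorer`,
#' `bodyparts` and `coords` (x / y / likelihood), one data row per frame.
#' Only the nose point is retained; low-confidence samples are linearly
#' interpolated from their neighbors (leading/trailing gaps are held at the
#' nearest valid sample).  Time is derived from the frame index and `fps`.
#'
#' @param path CSV file path.
#' @param fps video frame rate in frames/s (25 or 60 in the study protocols).
#' @param bodypart tracked point to extract (default `"nose"`).
#' @param min_confidence likelihood below which a sample is interpolated
#'   (default 0.6); set to 0 to disable interpolation.
#' @return a [pose_track()]; the attribute `interpolated_fraction` reports
#'   the fraction of interpolated frames as a QC metric.
#' @export
read_pose_table <- function(path, fps, bodypart = "nose", min_confidence = 0.6) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) stop_fmt("format error: expected 3 header rows in %s", path)
  parts <- strsplit(hdr[2], ",", fixed = TRUE)[[1]]
  coords <- strsplit(hdr[3], ",", fixed = TRUE)[[1]]
  want <- function(coord) {
    j <- which(trimws(parts) == bodypart & trimws(coords) == coord)
    if (length(j) != 1L)
      stop_fmt("format error: missing column '%s/%s' in header rows", bodypart, coord)
    j
  }
  jx <- want("x"); jy <- want("y"); jl <- want("likelihood")
  raw <- read.csv(path, skip = 3L, header = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (nrow(raw) == 0) stop_fmt("parse error: no data rows in %s", path)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(col %in% c("NA", "")))
    if (length(bad))
      stop_fmt("parse error: non-numeric value '%s' in column %s, data row %d",
               col[bad[1]], name, bad[1])
    v
  }
  x <- num(raw[[jx]], "x"); y <- num(raw[[jy]], "y")
  lik <- num(raw[[jl]], "likelihood")
  tr <- pose_track(x, y, fps = fps, confidence = lik)
  interpolate_low_confidence(tr, min_confidence)
}

#' Interpolate low-confidence pose samples
#'
#' Frames with confidence below `min_confidence` are replaced by linear
#' interpolation between the surrounding valid frames; gaps at either end are
#' held at the nearest valid sample.
#'
#' @param track a [pose_track()].
#' @param min_confidence threshold below which a sample is treated as missing.
#' @return the track with interpolated coordinates and attribute
#'   `interpolated_fraction`.
#' @export
interpolate_low_confidence <- function(track, min_confidence = 0.6) {
  ok <- track$confidence >= min_confidence
  frac <- mean(!ok)
  if (!any(ok)) stop_fmt("no frames at or above the confidence threshold")
  if (frac > 0) {
    idx <- seq_along(track$x)
    if (sum(ok) == 1) {
      track$x <- rep(track$x[ok], length(idx))
      track$y <- rep(track$y[ok], length(idx))
    } else {
      track$x <- approx(idx[ok], track$x[ok], xout = idx, rule = 2)$y
      track$y <- approx(idx[ok], track$y[ok], xout = idx, rule = 2)$y
    }
  }
  attr(track, "interpolated_fraction") <- frac
  track
}

#' Read a photometry CSV (columns time_s, f470, f415)
#'
#' The sampling rate is estimated as the reciprocal of the median time step;
#' jitter beyond 1% of that step or a non-monotone time column is an error.
#'
#' @param path CSV file path.
#' @return a [photometry_signal()].
#' @export
read_photometry_table <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop_fmt("parse error reading %s: %s", path, conditionMessage(e)))
  req <- c("time_s", "f470", "f415")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_fmt("format error: missing column(s) %s", paste(miss, collapse = ", "))
  if (nrow(df) < 2) stop_fmt("parse error: need at least 2 samples")
  if (any(diff(df$time_s) <= 0))
    stop_fmt("non-monotone time column (repeated or decreasing values)")
  photometry_signal(df$time_s, df$f470, df$f415)
}

# ---- structured configs (YAML or JSON by extension) ------------------------

read_config <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    # keep YAML-1.1 boolean-like scalars (y/n) literal: "y" is a coordinate
    # key in this schema, not TRUE
    yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                          "bool#no" = function(x) x))
}

check_keys <- function(cfg, required, optional, what) {
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop_fmt("%s config: missing required key(s): %s", what,
             paste(miss, collapse = ", "))
  unknown <- setdiff(names(cfg), c(required, optional))
  if (length(unknown))
    stop_fmt("%s config: unknown key(s): %s", what, paste(unknown, collapse = ", "))
}

#' Read an arena-layout config (YAML or JSON)
#'
#' Required keys: `arena_size_px` (2 numbers), `px_per_cm`, `chambers`
#' (list of `{label, x, y, edge_radius_px}`), `zone_mode`
#' (`radial`/`annulus`).  Optional: `annulus_margin_cm` (default 3),
#' `radial_radius_px` (default 100).  Unknown keys are rejected.
#'
#' @param path config file path (`.yaml`, `.yml` or `.json`).
#' @return an [arena_layout()].
#' @export
read_layout <- function(path) {
  cfg <- read_config(path)
  check_keys(cfg, c("arena_size_px", "px_per_cm", "chambers", "zone_mode"),
             c("annulus_margin_cm", "radial_radius_px"), "layout")
  ch <- cfg$chambers
  if (is.data.frame(ch)) ch_df <- ch
  else ch_df <- do.call(rbind, lapply(ch, function(c1) {
    check_keys(c1, c("label", "x", "y", "edge_radius_px"), character(), "chamber")
    data.frame(label = c1$label, x = c1$x, y = c1$y,
               edge_radius_px = c1$edge_radius_px)
  }))
  arena_layout(
    arena_size_px = as.numeric(cfg$arena_size_px),
    px_per_cm = cfg$px_per_cm,
    chambers = ch_df,
    zone_mode = cfg$zone_mode,
    annulus_margin_cm = if (is.null(cfg$annulus_margin_cm)) 3 else cfg$annulus_margin_cm,
    radial_radius_px = if (is.null(cfg$radial_radius_px)) 100 else cfg$radial_radius_px)
}

#' Read a session-protocol config (YAML or JSON)
#'
#' Required key: `phases` (list of `{label, start_s, end_s}`).  Optional:
#' `stimuli` (list of `{phase, chamber, stimulus}`), `treatment`.
#'
#' @param path config file path.
#' @return a [session_spec()].
#' @export
read_session <- function(path) {
  cfg <- read_config(path)
  check_keys(cfg, "phases", c("stimuli", "treatment"), "session")
  as_df <- function(x, keys, what) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(row) {
      check_keys(row, keys, character(), what)
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
  }
  phases <- as_df(cfg$phases, c("label", "start_s", "end_s"), "phase")
  stimuli <- if (is.null(cfg$stimuli)) NULL else
    as_df(cfg$stimuli, c("phase", "chamber", "stimulus"), "stimulus")
  session_spec(phases, stimuli,
               treatment = if (is.null(cfg$treatment)) NA_character_ else cfg$treatment)
}

#' Read a region-by-subject cell-count table
#'
#' Expects a CSV whose first column names the region and whose remaining
#' columns are per-subject integer counts.
#'
#' @param path CSV file path.
#' @return an integer matrix with region rownames and subject colnames.
#' @export
read_cell_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop_fmt("cell-count table needs a region column and counts")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop_fmt("cell counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

# ---- results ---------------------------------------------------------------

#' Write pipeline results to a directory
#'
#' Serializes a session's results: a JSON summary (`summary.json`) for scalar
#' results (indices, event counts, test statistics), each heatmap as a dense
#' matrix CSV plus a sidecar JSON recording bin size, origin, units and the
#' coordinate convention, and bout tables as CSV.  Floats are written with 9
#' significant digits so reruns on identical inputs are byte-stable.
#'
#' @param results a list with any of: `summary` (named list of scalars),
#'   `heatmaps` (named list of [heat_map()]), `bouts` (data.frame with
#'   `start_s`, `end_s`, `duration_s`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the character vector of files written.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop_fmt("cannot create output directory %s", out_dir)
  written <- character()
  if (!is.null(results$summary)) {
    p <- file.path(out_dir, "summary.json")
    s <- rapply(results$summary, f = function(v)
      if (is.double(v)) stable_num(v) else v, how = "replace")
    jsonlite::write_json(s, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  for (nm in names(results$heatmaps)) {
    hm <- results$heatmaps[[nm]]
    p <- file.path(out_dir, paste0("heatmap_", nm, ".csv"))
    chr <- matrix(formatC(stable_num(hm$grid), format = "g", digits = 9),
                  nrow(hm$grid))
    write.table(chr, p, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    side <- file.path(out_dir, paste0("heatmap_", nm, ".json"))
    jsonlite::write_json(
      list(bin_px = hm$bin_px, origin = hm$origin, units = hm$units,
           nrow = nrow(hm$grid), ncol = ncol(hm$grid),
           coordinates = "pixel space, origin top-left, y down; rows = y bins, cols = x bins"),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p, side)
  }
  if (!is.null(results$bouts)) {
    p <- file.path(out_dir, "bouts.csv")
    b <- results$bouts
    b[] <- lapply(b, function(v) if (is.double(v)) stable_num(v) else v)
    write.csv(b, p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read back a heatmap written by [write_results()]
#'
#' @param csv_path path to the dense matrix CSV.
#' @param sidecar_path path to the sidecar JSON; defaults to the CSV path
#'   with extension `.json`.
#' @return a [heat_map()].
#' @export
read_heat_map <- function(csv_path, sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  grid <- as.matrix(read.csv(csv_path, header = FALSE))
  dimnames(grid) <- NULL
  side <- jsonlite::fromJSON(sidecar_path)
  heat_map(grid, bin_px = side$bin_px, origin = side$origin, units = side$units)
}
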