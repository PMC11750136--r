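# Spatially binned occupancy/event maps and their correlation analyses.

bin_index <- function(coord, extent_px, bin_px) {
  nb <- ceiling(extent_px / bin_px)
  idx <- floor(coord / bin_px) + 1L
  idx[coord >= extent_px] <- nb   # right/bottom edge falls in the last bin
  pmin(pmax(idx, 1L), nb)
}

grid_dims <- function(layout, bin_px) {
  c(ny = ceiling(layout$arena_size_px[2] / bin_px),
    nx = ceiling(layout$arena_size_px[1] / bin_px))
}

check_inside <- function(x, y, layout, what) {
  out <- x < -1 | x > layout$arena_size_px[1] + 1 |
         y < -1 | y > layout$arena_size_px[2] + 1
  if (any(out))
    warning(sprintf("%d %s position(s) more than 1 px outside the arena; clamped to edge bins",
                    sum(out), what))
  sum(out)
}

accumulate_grid <- function(x, y, w, layout, bin_px) {
  dims <- grid_dims(layout, bin_px)
  ix <- bin_index(x, layout$arena_size_px[1], bin_px)
  iy <- bin_index(y, layout$arena_size_px[2], bin_px)
  grid <- matrix(0, dims["ny"], dims["nx"])
  for (i in seq_along(ix)) grid[iy[i], ix[i]] <- grid[iy[i], ix[i]] + w
  grid
}

#' Cumulative-time occupancy heatmap
#'
#' Each frame adds `1/fps` seconds to the bin containing the nose, so the
#' grid total equals the session duration exactly.  Positions more than 1 px
#' outside the arena are clamped into the edge bins with a warning.
#'
#' @param track a [pose_track()].
#' @param layout an [arena_layout()].
#' @param bin_px spatial bin size, pixels (default 50).
#' @return a [heat_map()] in seconds; attribute `n_clamped` counts clamped
#'   frames.
#' @export
occupancy_map <- function(track, layout, bin_px = 50) {
  n_out <- check_inside(track$x, track$y, layout, "nose")
  hm <- heat_map(accumulate_grid(track$x, track$y, 1 / track$fps, layout, bin_px),
                 bin_px = bin_px, units = "seconds")
  attr(hm, "n_clamped") <- n_out
  hm
}

#' Cumulative calcium-event heatmap
#'
#' Counts events per spatial bin; the grid total equals the event count.
#'
#' @param positions data.frame with `x`, `y` event positions in pixels (see
#'   [events_to_positions()]).
#' @param layout an [arena_layout()].
#' @param bin_px spatial bin size, pixels (default 50).
#' @return a [heat_map()] in counts.
#' @export
event_map <- function(positions, layout, bin_px = 50) {
  if (nrow(positions) == 0) {
    dims <- grid_dims(layout, bin_px)
    return(heat_map(matrix(0, dims["ny"], dims["nx"]), bin_px = bin_px,
                    units = "counts"))
  }
  n_out <- check_inside(positions$x, positions$y, layout, "event")
  hm <- heat_map(accumulate_grid(positions$x, positions$y, 1, layout, bin_px),
                 bin_px = bin_px, units = "counts")
  attr(hm, "n_clamped") <- n_out
  hm
}

#' Column-wise correlation of time and event heatmaps
#'
#' Pearson correlation between matching strips of the cumulative-time and
#' cumulative-event maps.  A "column" is a constant-x strip of the binned
#' arena image (the default); `margin = "row"` correlates constant-y strips
#' instead.  Strips where either map has zero variance have an undefined
#' correlation and are excluded from the valid count, mirroring the behavior
#' of the Pearson coefficient itself.
#'
#' @param time_map,evt_map [heat_map()]s with identical shape and bin
#'   geometry.
#' @param margin `"column"` (constant x) or `"row"` (constant y).
#' @param interior_only drop the first and last strip (arena border bins).
#' @return an object of class `correlation_profile`: data.frame with
#'   `index`, `r`, `n_bins`; attribute `n_valid` counts defined entries.
#' @export
column_correlation <- function(time_map, evt_map,
                               margin = c("column", "row"),
                               interior_only = FALSE) {
  margin <- match.arg(margin)
  if (!identical(dim(time_map$grid), dim(evt_map$grid)))
    stop_fmt("heatmap shapes differ")
  if (!isTRUE(all.equal(time_map$bin_px, evt_map$bin_px)))
    stop_fmt("heatmap bin sizes differ")
  a <- time_map$grid; b <- evt_map$grid
  if (margin == "row") { a <- t(a); b <- t(b) }
  idx <- seq_len(ncol(a))
  if (interior_only && length(idx) > 2) idx <- idx[-c(1, length(idx))]
  r <- vapply(idx, function(j) {
    u <- a[, j]; v <- b[, j]
    if (sd(u) == 0 || sd(v) == 0) NA_real_ else cor(u, v)
  }, numeric(1))
  out <- data.frame(index = idx, r = r, n_bins = nrow(a))
  attr(out, "n_valid") <- sum(!is.na(r))
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Ratio of calcium-event counts between two zones
#'
#' Counts detected events whose frame is labeled with each zone and forms
#' the ratio a/b (e.g. mouse zone over object zone, or novel over familiar).
#' Degenerate cases return markers, not errors: `Inf` when only the
#' denominator is empty, `NA` when both are.
#'
#' @param event_frames integer frame rows of the events (see
#'   [events_to_positions()]).
#' @param occupancy a [assign_zones()] result for the same track.
#' @param zone_a,zone_b zone labels (numerator, denominator).
#' @return a single number, possibly `Inf` or `NA`.
#' @export
zone_event_ratio <- function(event_frames, occupancy, zone_a, zone_b) {
  labels <- c(names(occupancy$times), "none")
  if (!(zone_a %in% labels) || !(zone_b %in% labels))
    stop_fmt("unknown zone label")
  z <- occupancy$zone[event_frames]
  a <- sum(z == zone_a); b <- sum(z == zone_b)
  if (a == 0 && b == 0) return(NA_real_)
  if (b == 0) return(Inf)
  a / b
}

#' Correlate zone event ratios with a behavioral index across a cohort
#'
#' Pearson correlation (two-sided) between per-animal event ratios and
#' behavioral indices; non-finite ratios (undefined or infinite markers) are
#' excluded and reported.
#'
#' @param ratio,index numeric vectors, one entry per animal.
#' @return list with `r`, `p`, `n` (finite pairs used) and `n_excluded`.
#' @export
ratio_index_correlation <- function(ratio, index) {
  if (length(ratio) != length(index)) stop_fmt("length mismatch")
  ok <- is.finite(ratio) & is.finite(index)
  if (sum(ok) < 3)
    stop_fmt("need at least 3 finite pairs (have %d)", sum(ok))
  ct <- cor.test(ratio[ok], index[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       n_excluded = sum(!ok))
}

#' Per-frame nose distance to a chamber center
#'
#' @param track a [pose_track()].
#' @param center numeric length-2 chamber center, pixels.
#' @param px_per_cm optional scale; when given, distances are returned in cm.
#' @return numeric vector of per-frame Euclidean distances.
#' @export
nose_distance_vector <- function(track, center, px_per_cm = NULL) {
  d <- sqrt((track$x - center[1])^2 + (track$y - center[2])^2)
  if (!is.null(px_per_cm)) d <- d / px_per_cm
  d
}
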