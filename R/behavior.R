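# Zone assignment and behavioral indices for the three-chamber recognition
# tests.

#' Assign each frame to an interaction zone
#'
#' In radial mode a frame is in chamber k's zone iff the nose-center distance
#' is strictly less than `radial_radius_px`; in annulus mode iff it falls in
#' `[edge_radius_px, edge_radius_px + annulus_margin_cm * px_per_cm)`.  When
#' several zones contain a frame it is assigned to the nearest chamber
#' center; exact ties go to `"none"` so no frame is double counted.
#' Interaction time per zone is the frame count divided by fps.
#'
#' @param track a [pose_track()] in the same pixel space as the layout.
#' @param layout an [arena_layout()].
#' @return an object of class `zone_occupancy`: list with `zone` (per-frame
#'   label, chamber label or `"none"`), `times` (named per-zone seconds) and
#'   `fps`.
#' @export
assign_zones <- function(track, layout) {
  ch <- layout$chambers
  n <- length(track)
  d <- vapply(seq_len(nrow(ch)), function(j)
    sqrt((track$x - ch$x[j])^2 + (track$y - ch$y[j])^2), numeric(n))
  d <- matrix(d, nrow = n)
  if (layout$zone_mode == "radial") {
    inzone <- d < layout$radial_radius_px
  } else {
    outer_r <- rep(ch$edge_radius_px + layout$annulus_margin_cm * layout$px_per_cm,
                   each = n)
    inner_r <- rep(ch$edge_radius_px, each = n)
    inzone <- d >= inner_r & d < outer_r
  }
  zone <- rep("none", n)
  hits <- rowSums(inzone)
  one <- hits == 1L
  if (any(one)) zone[one] <- ch$label[apply(inzone[one, , drop = FALSE], 1, which)]
  multi <- which(hits > 1L)
  for (i in multi) {
    di <- ifelse(inzone[i, ], d[i, ], Inf)
    nearest <- which(di == min(di))
    zone[i] <- if (length(nearest) == 1L) ch$label[nearest] else "none"
  }
  times <- setNames(numeric(nrow(ch)), ch$label)
  tab <- table(zone[zone != "none"])
  times[names(tab)] <- as.numeric(tab) / track$fps
  structure(list(zone = zone, times = times, fps = track$fps),
            class = "zone_occupancy")
}

#' @export
print.zone_occupancy <- function(x, ...) {
  cat(sprintf("<zone_occupancy> %d frames; in-zone seconds: %s\n",
              length(x$zone),
              paste(sprintf("%s=%.2f", names(x$times), x$times), collapse = ", ")))
  invisible(x)
}

#' Sociability index
#'
#' Total interaction time with the conspecific divided by the total
#' interaction time with conspecific and object combined.  0.5 is chance;
#' above 0.5 indicates preference for the conspecific.
#'
#' @param t_mouse,t_object interaction times in seconds (>= 0).
#' @return a value in `[0, 1]`, or `NA` when both times are zero (the index
#'   is undefined, not 0).
#' @export
sociability_index <- function(t_mouse, t_object) {
  stopifnot(t_mouse >= 0, t_object >= 0)
  total <- t_mouse + t_object
  ifelse(total == 0, NA_real_, t_mouse / total)
}

#' Discrimination index
#'
#' Interaction time with the novel stimulus divided by the total interaction
#' time with novel and familiar stimuli.  0.5 is chance; above 0.5 indicates
#' preference for novelty (intact recognition memory).
#'
#' @param t_novel,t_familiar interaction times in seconds (>= 0).
#' @return a value in `[0, 1]`, or `NA` when both times are zero.
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  stopifnot(t_novel >= 0, t_familiar >= 0)
  total <- t_novel + t_familiar
  ifelse(total == 0, NA_real_, t_novel / total)
}

#' Apply the saline-session exclusion rule
#'
#' In within-subject chemogenetic designs, subjects whose discrimination
#' index under saline treatment is below 0.5 (no evidence of intact memory at
#' baseline) are excluded; a DI of exactly 0.5 is retained, as the rule is a
#' strict "less than".
#'
#' @param sessions data.frame with columns `subject`, `treatment` and
#'   `discrimination_index`; every subject must have a `"saline"` row.
#' @param threshold exclusion threshold (default 0.5).
#' @return list with `retained` (the rows of subjects kept), `excluded`
#'   (report data.frame with `subject`, `discrimination_index`, `rule`).
#' @export
apply_exclusion <- function(sessions, threshold = 0.5) {
  req <- c("subject", "treatment", "discrimination_index")
  if (!all(req %in% names(sessions)))
    stop_fmt("sessions must have columns %s", paste(req, collapse = ", "))
  subjects <- unique(sessions$subject)
  sal <- sessions[sessions$treatment == "saline", , drop = FALSE]
  missing <- setdiff(subjects, sal$subject)
  if (length(missing))
    stop_fmt("missing saline session for subject(s): %s",
             paste(missing, collapse = ", "))
  di <- setNames(sal$discrimination_index, sal$subject)[as.character(subjects)]
  out <- subjects[di < threshold]
  excluded <- data.frame(
    subject = out,
    discrimination_index = as.numeric(di[as.character(out)]),
    rule = sprintf("saline DI < %g", threshold))
  list(retained = sessions[!(sessions$subject %in% out), , drop = FALSE],
       excluded = excluded)
}

#' Locomotion summary: distance traveled and mean velocity
#'
#' @param track a [pose_track()].
#' @param px_per_cm pixel-to-centimeter scale.
#' @return list with `distance_cm` (sum of per-frame displacements) and
#'   `mean_velocity_cm_s` (distance over session duration).
#' @export
locomotion <- function(track, px_per_cm) {
  if (length(track) < 2) stop_fmt("need at least 2 frames")
  stopifnot(px_per_cm > 0)
  d <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2)) / px_per_cm
  list(distance_cm = d,
       mean_velocity_cm_s = d / (length(track) / track$fps))
}

#' Restrict a pose track to a time window
#'
#' Convenience for per-phase analysis: keeps frames with
#' `start_s <= time < end_s`.
#'
#' @param track a [pose_track()].
#' @param start_s,end_s window bounds in seconds.
#' @return a [pose_track()] over the window (frame indices re-based).
#' @export
window_track <- function(track, start_s, end_s) {
  keep <- track$time_s >= start_s & track$time_s < end_s
  if (!any(keep)) stop_fmt("window contains no frames")
  pose_track(track$x[keep], track$y[keep], fps = track$fps,
             confidence = track$confidence[keep])
}
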