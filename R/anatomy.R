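# Tracing quantification: normalized presynaptic fractions, axis
# distributions, double-label and layer fractions, axon laminar profiles.

#' Normalized presynaptic fractions per region and subject
#'
#' Each region's count in a subject is divided by that subject's summed
#' count over the reference regions, controlling for transfection
#' variability across brains.  With the default reference (all regions in
#' the table) the fractions of the reference regions sum to 1 per subject.
#'
#' @param counts region x subject matrix of nonnegative integer counts
#'   (region rownames, subject colnames), e.g. from [read_cell_counts()] or
#'   [simulate_cellcounts()].
#' @param reference_regions regions whose per-subject sum is the
#'   denominator; defaults to all rows.
#' @return list with `fractions` (region x subject matrix) and `medians`
#'   (named per-region median across subjects).
#' @export
normalized_fractions <- function(counts, reference_regions = rownames(counts)) {
  if (is.null(rownames(counts))) stop_fmt("counts must have region rownames")
  miss <- setdiff(reference_regions, rownames(counts))
  if (length(miss))
    stop_fmt("reference region(s) not in table: %s", paste(miss, collapse = ", "))
  denom <- colSums(counts[reference_regions, , drop = FALSE])
  if (any(denom == 0))
    stop_fmt("zero reference sum for subject(s): %s",
             paste(colnames(counts)[denom == 0], collapse = ", "))
  fractions <- sweep(counts, 2, denom, "/")
  list(fractions = fractions,
       medians = apply(fractions, 1, median))
}

#' Antero-posterior axis distribution of labeled cells
#'
#' Histogram of cell coordinates (mm relative to bregma, anterior positive)
#' over half-open 1-mm bins, normalized by the total cell count, plus the
#' anterior/posterior split: a cell is anterior iff its coordinate is
#' strictly greater than `split_at` (cells exactly at the boundary count as
#' posterior).
#'
#' @param coords_mm numeric vector of cell positions along the axis.
#' @param bin_mm bin width, mm (default 1).
#' @param split_at split coordinate (default 0, bregma).
#' @return list with `breaks` (bin edges), `fraction` (per-bin fraction,
#'   sums to 1), `anterior_fraction`, `posterior_fraction`.
#' @export
axis_distribution <- function(coords_mm, bin_mm = 1, split_at = 0) {
  if (length(coords_mm) == 0) stop_fmt("need at least one cell")
  lo <- floor(min(coords_mm) / bin_mm) * bin_mm
  hi <- floor(max(coords_mm) / bin_mm) * bin_mm + bin_mm
  breaks <- seq(lo, hi, by = bin_mm)
  idx <- findInterval(coords_mm, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  anterior <- mean(coords_mm > split_at)
  list(breaks = breaks,
       fraction = counts / length(coords_mm),
       anterior_fraction = anterior,
       posterior_fraction = 1 - anterior)
}

#' Percentage of double-labeled projection neurons
#'
#' @param n_double number of neurons labeled by both tracers.
#' @param n_total number of reference-projection neurons (e.g.
#'   vCA1-projecting); must be positive and at least `n_double`.
#' @return percentage in `[0, 100]`.
#' @export
double_label_fraction <- function(n_double, n_total) {
  if (any(n_total <= 0)) stop_fmt("n_total must be positive")
  if (any(n_double < 0) || any(n_double > n_total))
    stop_fmt("n_double must lie in [0, n_total]")
  100 * n_double / n_total
}

#' Per-layer fractions of labeled neurons
#'
#' @param counts named numeric vector of nonnegative per-layer counts with
#'   positive total.
#' @return fractions summing to 1.
#' @export
layer_fractions <- function(counts) {
  if (any(counts < 0)) stop_fmt("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop_fmt("all-zero counts")
  counts / total
}

#' Max-normalized axon fluorescence laminar profiles
#'
#' Both profiles (background-subtracted fluorescence sampled across the
#' layer axis) are divided by the maximum of the distal profile, and the
#' area under each normalized curve is computed by the trapezoid rule.
#'
#' @param distal,proximal equal-length numeric intensity series.
#' @param depth optional axis positions; defaults to unit spacing
#'   `0:(m - 1)`.
#' @return list with `distal`, `proximal` (normalized series), `depth`,
#'   `auc_distal`, `auc_proximal`.
#' @export
laminar_profile <- function(distal, proximal, depth = NULL) {
  m <- length(distal)
  if (length(proximal) != m) stop_fmt("profiles must have equal length")
  if (is.null(depth)) depth <- seq_len(m) - 1
  if (length(depth) != m) stop_fmt("depth axis length mismatch")
  peak <- max(distal)
  if (peak <= 0) stop_fmt("maximum of the distal profile must be positive")
  nd <- distal / peak
  np <- proximal / peak
  list(distal = nd, proximal = np, depth = depth,
       auc_distal = trapezoid(depth, nd),
       auc_proximal = trapezoid(depth, np))
}
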