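---
title: "Quantifying recognition-memory experiments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying recognition-memory experiments: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recogmem)
```

# Scope

`recogmem` quantifies the standard measurements of rodent recognition-memory
experiments: three-chamber social and novel-object tests scored from
pose-tracked nose points, fiber-photometry calcium signals recorded from a
projection-defined neuronal population, the spatial relationship between
occupancy and calcium events, freezing in fear-conditioning sessions,
retrograde/monosynaptic tracing cell counts, and photo-evoked synaptic
currents in slice recordings. Everything upstream of these quantities —
tracking networks, atlas registration, acquisition software, imaging — is out
of scope: the package starts from exported tables (pose CSVs, photometry
time series, pixel-change series, count tables, sweep matrices).

Because raw in-vivo recordings of this kind are rarely deposited, the package
treats a synthetic-data generator as a first-class module: every analysis
stage can be validated against programmed ground truth, and the test suite
does exactly that.

# Behavioral scoring

A session is a `pose_track` (nose x, y in pixel space, origin top-left,
y down, 0-based frames) plus an `arena_layout` describing the chambers. Two
interaction-zone conventions are implemented, selected by `zone_mode`:

* **radial** — the nose is interacting iff its distance to the chamber
  center is strictly below `radial_radius_px` (100 px for social tests,
  50 px for object tests at the reference magnification);
* **annulus** — the zone is the ring from the chamber edge to 3 cm beyond
  it (`annulus_margin_cm * px_per_cm` pixels).

Boundary frames are excluded by the strict inequality; frames inside several
zones go to the nearest center, exact ties to `"none"` so no frame is
double-counted. Interaction time is frame count over fps — no sub-frame
interpolation, matching frame-based tracking.

The indices are ratios of interaction times: sociability
$t_\mathrm{mouse}/(t_\mathrm{mouse}+t_\mathrm{object})$ and discrimination
$t_\mathrm{novel}/(t_\mathrm{novel}+t_\mathrm{familiar})$, both 0.5 at
chance. When both times are zero the index is undefined and reported as
`NA`, never 0. The within-subject chemogenetic design retains a subject only
if its saline-treatment discrimination index is at least 0.5
(`apply_exclusion`, strict `<` at the boundary).

Low-confidence tracking samples (likelihood < 0.6 by default) are linearly
interpolated from neighbors, held at the nearest valid frame at the ends;
the interpolated fraction is attached to the track as a QC metric.
Interpolated frames participate in zone assignment.

# Photometry conditioning and event detection

The conditioning chain mirrors vendor practice: order-4 Butterworth low-pass
at 40 Hz applied forward-backward (zero phase, DC gain 1), z-scoring of the
calcium-dependent channel against a baseline window (whole session by
default; any window of at least 10 s may be chosen), and anti-aliased
downsampling onto the `k/60` s grid to match 60 fps video. Zero-phase
filtering uses odd-reflection padding at both ends so a signal with nonzero
mean enters and leaves the filter without edge transients.

The isosbestic channel (415 nm) is carried through the chain but not
subtracted by default; `isosbestic_correct()` exposes least-squares motion
regression for recordings that need it. This keeps the default chain an
exact implementation of the stated processing, while making the correction
an explicit, auditable choice.

A **calcium event** is an upward crossing of the z-score:
$z_{i-1} \le \theta < z_i$ with $\theta = 2.58$, the two-sided normal
quantile at $\alpha = 0.01$. One excursion counts once regardless of
duration. The threshold is a parameter; 2.58 is the default.

## The refractory parameter

Crossing detection on a slow calcium sensor has a known failure mode: the
transient's decay re-approaches the threshold slowly, and noise riding on
the decay produces several crossings per transient. In synthetic sessions
with the default kernel (rise 0.05 s, decay 1 s, peak 4 z) the raw detector
reported ~1.4 crossings per true transient, with echo crossings 0.5–1.1 s
after the onset. The detector therefore exposes a refractory period
(default 0 s, i.e. the literal crossing rule); the session-level pipeline
uses 1.5 s — the decay-to-threshold time (~0.45 s for a 4-z transient
crossing 2.58) plus a noise margin. At sparse event rates this yields one
detection per transient and >90% of detections within 0.25 s of the true
onset (the crossing necessarily lags the onset by the rise time, so
agreement is assessed at that scale).

# Spatial maps and the occupancy–activity correlation

Occupancy and event maps share one accumulator: 50-px bins (half-open
$[k\,b, (k+1)b)$; the right/bottom arena edge falls in the last bin), rows
indexing y and columns x. Each frame deposits $1/\mathrm{fps}$ seconds; each
event deposits one count. Mass conservation — grid total equals session
duration, respectively event count — is asserted in the test suite at
$10^{-9}$. Positions more than 1 px outside the arena are clamped into edge
bins and flagged.

`column_correlation` computes a Pearson coefficient per constant-x strip of
the two maps (per-row optionally). Strips with zero variance in either map
have no defined correlation and are excluded from the valid count rather
than coerced to 0. `zone_event_ratio` counts detected events by zone label
and returns `Inf`/`NA` markers for empty denominators; cohort-level
correlation (`ratio_index_correlation`) excludes non-finite ratios and
reports how many were dropped.

# Freezing

Freezing is a run of consecutive frames whose changed-pixel fraction is
strictly below 0.1% lasting strictly more than 1 s: a 25-frame run at
25 fps (exactly 1 s) is not a bout, 26 frames is. Percent freezing per
protocol phase clips bouts at window edges. The module consumes per-frame
pixel-change fractions; computing those from video is upstream acquisition.

# Tracing quantification

Regional presynaptic counts are normalized per subject by the summed count
over a set of reference regions, controlling for transfection variability;
with the shipped four-region table (endopiriform, basolateral amygdala,
lateral and medial septum across five brains) the per-subject reference
fractions sum to 1 and the across-subject medians round to 0.45 / 0.24 /
0.08 / 0.21. Antero-posterior distributions use half-open 1-mm bins
normalized by total cell count; a cell exactly at the split coordinate
(bregma) counts as posterior — a boundary convention the field leaves
unstated, here documented and tested rather than left implicit. Double-label percentages, per-layer
fractions, and max-normalized axon fluorescence profiles (normalized by the
distal subregion's maximum, AUC by trapezoid) complete the module.
Fluorescence profiles are expected background-subtracted on input, since
the subtraction procedure belongs to the imaging pipeline.

# Slice electrophysiology

Responses are classified on the averaged trace (3–6 photo-stimulation
repetitions). Baseline mean and SD come from the 100 ms before stimulus
onset; the response window runs from onset to 50 ms after it. A response
smaller than 2 baseline SDs is a **zero response** and its amplitudes are
reported as 0. The criterion statistic is the window extremum in the
expected polarity by default (inward EPSC at −70 mV, outward IPSC at
+12 mV), with an unsigned option.

The extremum statistic deserves a caveat it rarely gets: on a noise-only
trace, the extremum of several hundred baseline-distributed samples exceeds
2 SD almost surely, so the criterion is anticonservative as a pure
false-positive control and earns its keep only because genuine evoked
responses are far larger than baseline noise. `classify_response` therefore
also offers `stat = "mean"` (the window average against the same 2-SD
yardstick), whose null specificity exceeds 97% — the variant used in the
calibration test. Peak detection accuracy is validated on injected
responses instead.

Connection probability is the positive fraction per laminar group.
Per-slice normalization divides each neuron's amplitude by the slice
**mean** (so normalized values average 1 within a slice); the mean was
chosen over the sum because published normalized medians cluster near 1 for
3–4 cells per slice, and a `mode = "sum"` flag preserves the alternative.
The excitation–inhibition comparison pairs each cell's EPSC and IPSC
magnitudes and flags inhibition dominance (`|IPSC| > |EPSC|`, equality
sitting on the unitary line).

# Statistical contracts

`paired_compare` (Wilcoxon signed-rank) removes zero differences, requires
five informative pairs, and computes the exact two-sided p for up to 25
pairs by dynamic programming over all sign patterns with midranks — this
keeps the canonical worked example (six pairs shifted by a constant,
p = 2/2⁶ = 0.03125) exact even though the differences are tied, which the
stock exact path refuses. Larger samples use the normal approximation with
tie and continuity corrections. `group_compare` wraps one-way ANOVA with
Tukey–Kramer post-hocs (valid for unequal group sizes; for two groups it
reduces to the pooled t-test through the $q = \sqrt2\,|t|$ identity), or —
interpreting the unusual "ANOVA with post-hoc Kruskal–Wallis" pairing —
rank-based pairwise comparisons with Holm correction alongside the
Kruskal–Wallis omnibus. `correlate` is Pearson with two-sided p. The Grubbs
single-outlier screen (two-sided, closed-form t-based critical value,
α = 0.05) is available but off by default and reports the removed index
when applied.

Calibration: over 10⁴ seeded null replicates, the signed-rank test at
n = 20 pairs rejects at 4.8% (its exact attainable level below 0.05 is
0.0484 — computed analytically from the signed-rank distribution, which is
why the calibration uses 20 pairs rather than a size where the discrete
test cannot get near 5%), and Pearson at n = 8 rejects at 5.1%.

# The synthetic-data generator

The generator emulates the statistical structure the analyses rely on, not
the biophysics:

* **Trajectory** — a reflecting Gaussian random walk (step SD 2.5 px/frame
  at 60 fps ≈ 15 cm/s in a 500-px, 50-cm arena) with a latent behavioral
  state: free diffusion, or attraction to one chamber, entered with
  probability proportional to the chamber's gain and held with persistence
  0.98 per frame (geometric dwells, mean ~0.8 s). Attraction adds a drift
  of gain × step SD toward the chamber center. Occupancy rises with gain;
  equal gains give a discrimination index of ~0.5, and gains 0.8–1.6 span
  DI ≈ 0.5–0.9, bracketing published cohort medians (~0.66). The inner
  loop is compiled (Rcpp) and uses R's RNG, so runs are seed-reproducible.
* **Calcium coupling** — an inhomogeneous Poisson process thinned per
  behavioral frame, rate = baseline (0.1 events/s) × per-zone multiplier
  (3 in the novel zone by default, emulating novelty-biased activity).
  Each event adds a peak-normalized double-exponential transient
  (rise 0.05 s, decay 1 s, peak 4 z) on unit Gaussian noise; the
  isosbestic channel carries noise only. Ground-truth event times are
  returned. The baseline rate was chosen so that transient power does not
  dominate the session variance — at rates much above ~0.3 events/s the
  z-score denominator inflates until single transients no longer reach
  2.58, which is a property of whole-session z-scoring, not of the
  detector.
* **Pixel change, counts, sweeps** — Gaussian series straddling the 0.1%
  freezing threshold with programmed bouts; negative-binomial region ×
  subject count tables (Poisson in the infinite-dispersion limit);
  exponential-decay current sweeps in Gaussian baseline noise.

All generators are pure functions of parameters and seed; a master seed
expands into per-component substreams through a documented affine rule
(`substream_seed`), so stages can be re-simulated independently.

What the generator does **not** emulate: photobleaching and slow drift,
motion artifacts shared across photometry channels, sensor nonlinearity,
body-pose-dependent occlusion of the nose point, non-Poisson burstiness of
population activity, and correlated electrode noise. Passing tests
demonstrate that the analysis code recovers what it claims from data with
known structure — not that real recordings satisfy that structure.

## Problem sizes in the validation suite

The recovery analyses use cohorts of 8 subjects × 600 s at 60 fps
(matching the published session design) with 100 replicate cohorts for the
correlation-sign and rate-ratio checks; the detection oracle uses 1000
random traces; statistical calibration uses 10⁴ null replicates. One
replicate cohort takes ~3 s on one core.

# Numerical conventions

* Strict inequalities at every stated threshold (zone radius, freezing
  threshold and duration, exclusion rule), each with a boundary test.
* Half-open spatial and histogram bins; right/bottom edges into the last
  bin; the bregma split coordinate is posterior.
* Zero-variance strips/columns yield `NA` correlations and are excluded
  from counts; degenerate ratios propagate as `Inf`/`NA` markers and are
  excluded (and counted) at cohort level.
* Serialized floats carry 9 significant digits; rewriting identical
  results is byte-identical.
* Filtering is zero-phase with odd-reflection padding; pad length scales
  with the filter's settling time.

# Known limitations

The event detector is the literal threshold-crossing rule plus an optional
refractory period — no deconvolution, no amplitude estimation; at sustained
rates above ~1/decay-constant events merge and counts saturate, which is
why rate-multiplier recovery is assessed on cohort-pooled ground-truth
rates rather than per-subject detected-count ratios. Whole-session
z-scoring makes the event count scale-invariant but couples detectability
to session-wide activity level. The freezing module trusts the upstream
pixel-change computation. The anatomy module quantifies counts it is given;
segmentation and registration quality are upstream concerns.
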