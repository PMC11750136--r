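Package: recogmem
Title: Quantitative Analysis of Recognition-Memory Behavior, Fiber
    Photometry, Tracing and Slice Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying recognition-memory
    experiments in mice: zone-based scoring of three-chamber social and
    novel-object tests from pose-tracking nose points (sociability and
    discrimination indices, locomotion, saline-session exclusion),
    conditioning and event detection for fiber-photometry calcium signals
    (zero-phase Butterworth filtering, z-scoring, downsampling to the
    behavioral frame rate, threshold-crossing event trains), spatially
    binned occupancy and calcium-event heatmaps with column-wise
    correlation and zone event ratios, freezing detection from per-frame
    pixel-change fractions, normalization of retrograde and monosynaptic
    tracing cell counts (regional fractions, antero-posterior axis
    distributions, double-label and laminar fractions, axon fluorescence
    profiles), and photo-evoked synaptic response metrics (2-SD response
    criterion, peak and mean amplitudes, connection probability,
    per-slice normalization, excitation-inhibition comparison).  A
    synthetic-data generator with known ground truth (biased random-walk
    trajectories, location-coupled calcium transients, pixel-change
    series, overdispersed count tables, ephys sweeps) makes every stage
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
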