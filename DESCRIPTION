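Package: spatialtuning
Title: Simulation and Detection of Place-Cell Spatial Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for studying how place cells are detected from spike trains
    and trial-by-bin firing-rate maps. Provides a generative simulator of
    Gaussian place fields on linear tracks and 2D grids with controllable peak
    rate, width, baseline, additive noise, trial-to-trial field jitter and
    presence ratio; occupancy-normalised rate-map construction from spike
    times and position traces with speed filtering, smoothing and
    quality-control rules; the two spatial-tuning statistics in common use
    (Skaggs spatial information in bits/spike and the one-way ANOVA
    F-statistic over spatial bins); circular-shift permutation nulls at the
    spike and rate-matrix level with fixed-threshold and percentile
    classification; estimation of eight per-neuron place-field features; and
    PCA of the population feature space. A config-driven harness runs
    parameter sweeps and binning/smoothing sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
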