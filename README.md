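# spatialtuning

Place cells — hippocampal neurons that fire when an animal occupies a
particular location — are detected with different statistics in different
literatures: rodent studies usually score neurons by Skaggs spatial
information (SI, bits/spike), often with a fixed cutoff such as 0.25
bits/spike, while human intracranial studies usually test a one-way ANOVA
F-statistic over spatial bins against shuffled surrogates. The two
statistics respond to different properties of a firing field, so the choice
of pipeline changes which neurons are called place cells.

`spatialtuning` is an R toolbox for studying exactly that, aimed at
electrophysiologists and methodologists comparing detection pipelines. It
provides:

* a generative simulator of Gaussian place fields on linear tracks and 2D
  grids with known ground truth (peak rate, width, baseline, additive noise,
  per-trial field jitter, presence ratio), producing trial-by-bin rate
  matrices or Poisson spike trains;
* occupancy-normalised trial-by-bin rate maps from spike times and position
  traces, with speed filtering, Gaussian smoothing, re-binning and the usual
  quality-control rules;
* both tuning statistics, permutation nulls (circular spike-train shifts, or
  circular row shifts for rate matrices), fixed-threshold and
  percentile-rule classification, and the four-way comparison of criteria;
* estimation of eight per-neuron place-field features and PCA of the
  population feature space;
* a config-driven CLI harness for parameter sweeps and binning/smoothing
  sensitivity analyses.

## The two statistics

For occupancy probability `p(x)`, mean rate `g(x)` in bin `x` and
occupancy-weighted overall mean `ḡ = Σ p(x) g(x)`, the spatial information
per spike is

    SI = Σ_x p(x) · (g(x)/ḡ) · log2( g(x)/ḡ )        [bits/spike]

computed on the trial-averaged map, so it measures peak-to-average firing
contrast and is blind to trial-to-trial variability. The ANOVA approach
treats spatial bins as groups and per-trial rates as observations:

    F = MS_between / MS_within

which is large only when firing differs across positions *consistently over
trials*. The simulator makes the dissociation explicit: SI peaks for narrow,
high-contrast fields and falls with added baseline; F peaks at intermediate
widths and collapses under trial-level noise, field jitter, or field
dropout.

## Worked example

```r
library(spatialtuning)

params <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1,
                             noise_sd = 1, jitter_max = 0, presence = 1)
m <- simulate_trials(params, geometry(50), n_trials = 30, seed = 7)
m
#> <trial_rate_matrix> 30 trials x 50 bins (1D)
#>   mean rate 2.55 Hz, peak 13.4 Hz, 0 missing bins

test_spatial_tuning(m, n_surrogates = 1000, seed = 8)
#> <tuning_test>
#>   SI = 0.6498 bits/spike (perm p = 0.000999, significant; threshold 0.25: above)
#>   F  = 306.7 (perm p = 0.000999, significant)
#>   category: both (perm/perm), both (threshold/perm); 1000 surrogates, rate_row_shift
```

A sharply tuned 10 Hz field on a 1 Hz baseline carries 0.65 bits per spike
(above the 0.25 threshold and above the 95th percentile of 1000 circular
row-shift surrogates) and an F of ~307 (30 consistent trials, noise SD 1 Hz)
— a clear place cell under every criterion, so the four-way category is
"both". The eight field features recover the ground truth:

```r
round(estimate_features(m), 3)
#>         peak_rate          avg_rate       peak_to_avg       field_width
#>            10.800             2.548             4.238            13.000
#>          n_fields field_consistency    presence_ratio        even_odd_r
#>             1.000             1.000             1.000             0.994
```

Sweeping field width reproduces the central non-monotonic finding — the two
metrics are optimised by different field sizes:

```r
spec <- sweep_spec("width", 1, 20, n_samples = 200, fixed = params,
                   n_trials = 30, seed = 9)
run_sweep(spec)
#> <sweep_result> 'width' over [1, 20], 200 neurons
#>   mean SI maximal at width = 3.00503; mean F maximal at width = 7.49246
```

`plot()` on the sweep result draws the paired SI/F curves; `plot()` on a
`pca_features()` result draws the feature biplot.

## Command line

A thin wrapper over the same functions ships in `inst/cli/spatialtuning.R`:

    Rscript inst/cli/spatialtuning.R sweep --config cfg.yaml --seed 1 --out-dir out/

with subcommands `simulate`, `sweep`, `detect`, `features`, `pca`,
`sensitivity`, `report`. Configs are flat key-value YAML; every output
directory gets a JSON manifest (config, seeds, package version, row counts)
and a given config + seed reproduces every table byte-for-byte.

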