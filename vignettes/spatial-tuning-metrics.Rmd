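---
title: "Simulating place fields and comparing spatial-tuning statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating place fields and comparing spatial-tuning statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialtuning)
```

## The generative model

Each simulated neuron's expected firing rate over a discretised environment
(a 1D track of `n_bins` equal bins, default 50, or a 2D grid, default
10 × 10) is a Gaussian bump plus a constant background:

$$G(x) = A \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right) + B_0 + N(x),
\qquad N(x) \sim \mathcal{N}(0, \sigma_n^2)$$

with the isotropic two-dimensional analogue on grids. On every trial the
noise term is redrawn independently per bin; two further parameters degrade
trial-to-trial reliability without touching the single-trial shape:

| parameter | meaning | units | default |
|---|---|---|---|
| `peak` (A) | field amplitude | Hz | 10 |
| `mu` | field centre (0-based bin coordinate) | bins | 25 |
| `sigma` | field width (Gaussian SD) | bins | 5 |
| `baseline` (B0) | constant background rate | Hz | 1 |
| `noise_sd` | per-bin, per-trial rate noise SD | Hz | 1 |
| `jitter_max` | per-trial field-centre offset bound | bins | 0 |
| `presence` | probability the field is expressed on a trial | — | 1 |

The defaults are the fixed values used whenever one parameter is swept and
the others held constant: a 10 Hz field of width 5 bins on a 1 Hz baseline
with 1 Hz noise over 30 trials is a sharply tuned but realistically noisy
dorsal-CA1-like neuron, and it leaves every sweep room to move in both
directions. Sweep ranges follow the conventional choices: amplitude 1–20 Hz,
width 1–20 bins, baseline 0.5–5 Hz, noise 0.5–5 Hz, jitter 0–5 bins,
presence 0.1–1.

Modelling choices the equations leave open:

* **Negative rates.** Gaussian noise can drive rates negative; rates are
  physical, so they are clipped at zero before any metric. A `clip = FALSE`
  escape hatch exists for numerical oracle checks only.
* **Noise on absent trials.** When the field is not expressed, the trial is
  baseline plus noise — noise is never switched off.
* **Jitter sign.** Offsets are drawn uniformly from `[0, jitter_max]`
  (one-directional, as the generative description reads); a `"symmetric"`
  mode drawing from `[-jitter_max, jitter_max]` is provided, and the mode
  used is recorded in each matrix's provenance.
* **Edges.** Shifted or broad fields are truncated at the track edge — a
  linear track has walls, so there is no wrap-around.
* **Presence and the trial average.** Plain field dropout scales the
  trial-averaged field by the presence ratio, so it changes the average
  map's contrast as well as its reliability. To isolate reliability — the
  regime in which dropout degrades consistency while the expected
  trial-averaged profile stays fixed — `simulate_trials(presence_rescale =
  TRUE)` divides the amplitude on expressed trials by the presence ratio.
  Presence sweeps use this mode by default (other sweeps are unaffected,
  since rescaling is a no-op at presence 1); without it, the spatial
  information score inherits a strong presence dependence through the
  average map and the two statistics no longer dissociate.
* **Seeding.** Populations derive per-neuron sub-seeds from the master seed
  by a counter scheme, `(seed + 1009 i) mod 2147483587`, so any single
  neuron is reproducible in isolation and identical `(params, seed)` give
  bit-identical matrices.

## What the simulator does and does not emulate

The generator models trial-by-bin *rates* directly, which gives exact
control of field properties. It does not model spike-level variability
(except through the optional Poisson spike synthesis), theta modulation or
phase precession, multi-field neurons (multiple fields arise only through
noise), running-speed modulation, or behavioural sampling biases —
occupancy is uniform by construction. Tests passing on these simulations
therefore demonstrate properties of the *statistics*, not of any recording;
empirical effect sizes (proportions of significant neurons, observed F
cutoffs) depend on data properties the simulator deliberately holds fixed.

The Poisson spike path (`synthesize_spikes()`) lays trials back-to-back
along a constant-speed traversal. One consequence worth knowing: if every
trial has the same duration, the session is exactly periodic and a circular
time shift is equivalent to a spatial rotation — to which both statistics
are invariant — so the spike-level null has no power. Varying per-trial
durations (supported directly) restores the misalignment that the
circular-shift null relies on; empirical sessions are aperiodic for free.

## Rate maps, smoothing, binning

Empirical rate maps are spike counts divided by occupancy seconds, per trial
and bin, with samples slower than the speed floor excluded. Bins a trial
never occupied are *missing*, not zero: they are excluded from the spatial
information sum (with occupancy renormalised) and enter the ANOVA as absent
observations in an unbalanced layout. Bins are half-open intervals with
0-based indices; a position exactly at the track end belongs to the last
bin. Each tracking sample is credited with the time between the midpoints
to its neighbours (trial windows bound the ends), so a constant-speed
traversal yields exactly uniform occupancy.

Smoothing convolves each trial row with a Gaussian kernel truncated at 3 SD
and renormalised at the edges so the weights sum to one at every bin. The
renormalised operator preserves flat maps exactly and conserves mass
carried by bins farther than two kernel radii from an edge; mass closer to
an edge is redistributed rather than conserved (the usual behaviour of
occupancy-style renormalisation). Smoothing is never applied implicitly —
it is a pipeline choice, and the sensitivity harness treats it as an
explicit variant. Re-binning averages adjacent bins and requires the coarse
bin count to divide the fine one, so the aggregation is clean; populations
meant for 10/20/30-bin comparisons are generated on 60 bins.

## The two statistics and their numerical edges

Spatial information uses the occupancy-weighted overall mean in the
denominator (for simulated matrices occupancy is uniform; an unweighted
variant is available by passing uniform occupancy explicitly). Zero-rate
bins contribute zero via the $x \log x \to 0$ limit; a silent neuron yields
`NaN` flagged `"silent neuron"`; negative rates are an error, not a warning.

The ANOVA F is computed by the direct between/within decomposition with
per-group counts (the permutation machinery needs on the order of $10^6$
evaluations per study, so the statistic is computed in vectorised form; the
test suite verifies it against R's independent linear-model ANOVA to
$10^{-10}$ relative error on a thousand random matrices, unbalanced cases
included). Zero within-variance with structure between bins gives `Inf`
flagged as degenerate; an all-constant matrix gives `NaN`. Both metrics
treat bins as unordered categories, which is why 1D and 2D environments are
handled identically after flattening.

## Permutation testing

Spike-level nulls circularly shift the session-wide spike train by offsets
uniform on `[min_shift, T - min_shift]` (`min_shift` defaults to 1 s to
exclude near-identity shifts); every surrogate map is rebuilt with exactly
the observed map's binning, speed filter and smoothing. Rate-level nulls —
the default for simulated matrices, which have no spikes — circularly shift
every trial row by an independent bin offset, preserving each row's values
as a multiset. Because row shifts leave the grand mean and total sum of
squares untouched, both null statistics depend on a surrogate only through
its column means, which is what makes 1000 surrogates per neuron cheap; the
fast path is verified against metrics computed on materialised surrogates.

Significance follows the strict percentile rule: a neuron is significant
when its observed statistic *exceeds* the 95th percentile of its own null
(ties are not significant). The counting p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$ is reported alongside. No
multiple-comparison correction is applied across neurons — the convention
is per-neuron $\alpha = 0.05$. On 1000 no-field neurons (amplitude zero)
both tests' rejection rates sit inside the 99% binomial band around 0.05;
this calibration is exact by symmetry, because i.i.d. noise within rows
makes the observed matrix exchangeable with its own row rotations.

## Features and PCA

Eight per-neuron features summarise field structure and reliability: peak
rate, average rate, their ratio, field width (all bins above 20% of the
trial-averaged peak), number of fields (contiguous supra-threshold runs of
at least `min_width_bins`, default 2 — a one-bin blip is noise, not a
field), field consistency (fraction of trials whose peak bin lands within
±3 bins of the overall peak; per-trial ties break toward the lower index),
presence ratio (fraction of trials with strictly positive firing inside the
detected field region, on unsmoothed maps), and the even–odd map
correlation (trial 1 is odd). The threshold is relative to the raw peak —
baseline is not subtracted — and an exactly flat map has no fields by
definition. Degenerate cases (no detected field, constant half-maps) yield
`NaN` with named flags rather than silent numbers.

With a nonzero baseline the estimated presence ratio saturates at 1 — some
bin in the field region almost always fires — so recovering a programmed
presence requires baseline-free simulations; this mirrors the empirical
practice of computing presence on thresholded activity.

PCA of the neuron-by-feature matrix z-scores columns by default (features
have incommensurate units, so comparable loadings require it), drops
zero-variance features with a warning, excludes rows with non-finite
entries with a report, and fixes component signs by making each component's
largest-magnitude loading positive, so biplots are reproducible. All
components are retained; the count needed for 90% cumulative variance is
reported. On a mixed population spanning all six parameter sweeps, the SI
gradient in the leading component plane aligns positively with the
peak-to-average loading and the F gradient with the even–odd correlation
loading — the dissociation stated as geometry.

## Problem sizes and test design

The test suite reproduces the study's directional findings at sizes chosen
so that true effects dominate Monte-Carlo error while the whole suite stays
interactive: 200 neurons per width value for the sweep optima (the SI
optimum at width ≤ 3 bins and the F optimum at 6–8 bins on a 50-bin track),
50–100 neurons per value for noise, jitter and presence sweeps, 1000
neurons × 1000 surrogates for calibration, and 40-neuron populations for
smoothing/binning directions. Two property-specific choices deserve note.
First, the fixed-threshold fragility test uses weak, narrow fields
(amplitude 0.5–6 Hz, width 2 bins on a 60-bin track): threshold fragility
is a statement about neurons *near* the cutoff, and a population of
strongly tuned cells sits too far from 0.25 bits/spike for any binning to
move it across. Second, field-consistency monotonicity in jitter is
asserted on the grid {0, 2.5, 5} bins: offsets smaller than the ±3-bin
consistency window barely move the estimator, so adjacent integer jitters
differ by less than desk-scale Monte-Carlo error.

## Known limitations

* Feature extraction is defined for 1D maps; 2D matrices are analysed by
  the two metrics only.
* The simulator's uniform occupancy means SI's occupancy weighting is only
  exercised through the empirical (spike) path and explicit occupancy
  arguments.
* The rate-level null assumes bins are exchangeable within a trial after
  rotation, which holds for i.i.d. noise but would be optimistic for data
  with strong within-trial autocorrelation; the spike-level null inherits
  the temporal autocorrelation of the train and is the appropriate choice
  for empirical sessions.
* Quality-control rules operate on per-neuron summaries supplied by the
  caller; the package does not sort spikes or reconstruct trajectories.
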