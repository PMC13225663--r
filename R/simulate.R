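#' Noiseless expected firing-rate profile of a place field
#'
#' Evaluates the deterministic part of the generative model at every bin:
#' a Gaussian bump of amplitude `peak` centred at `mu` plus the constant
#' baseline. On a linear track the rate at bin `x` is
#' `peak * exp(-(x - mu)^2 / (2 sigma^2)) + baseline`; on a grid the
#' isotropic 2D analogue is used and the result is returned flattened in
#' row-major bin order (see [bin_coords()]).
#'
#' @param params a [place_field_params()] object.
#' @param geom a [geometry()] object; `mu` must lie inside it.
#' @return numeric vector of expected rates (Hz), length `geom$total_bins`.
#' @examples
#' p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1)
#' prof <- tuning_profile(p, geometry(50))
#' prof[26]  # value at bin 25: peak + baseline = 11 Hz
#' @export
tuning_profile <- function(params, geom) {
  stopifnot(inherits(params, "place_field_params"), inherits(geom, "geometry"))
  check_mu_in_range(params, geom)
  gaussian_peak(params$peak, params$mu, params$sigma, geom) + params$baseline
}

# Gaussian bump evaluated at all bin centres; no baseline, no noise.
gaussian_peak <- function(peak, mu, sigma, geom) {
  co <- bin_coords(geom)
  if (geom$dims == 1L) {
    d2 <- (co - mu)^2
  } else {
    d2 <- (co[, 1] - mu[1])^2 + (co[, 2] - mu[2])^2
  }
  peak * exp(-d2 / (2 * sigma^2))
}

#' Trial-by-bin firing-rate matrix container
#'
#' The universal container consumed by the tuning metrics, permutation tests
#' and feature estimation: an `n_trials` x `total_bins` matrix of firing
#' rates (Hz) plus its [geometry()]. 2D grids are stored flattened (row-major
#' bin order) with the geometry retained. Bins with no occupancy (empirical
#' maps) are `NA`, not zero.
#'
#' @param rates numeric matrix, trials in rows, bins in columns; all finite
#'   values must be >= 0.
#' @param geom a [geometry()] whose total bin count matches `ncol(rates)`.
#' @param provenance free-form list recording how the matrix was produced
#'   (simulation seed and parameters, or an empirical session id).
#' @return An object of class `"trial_rate_matrix"`.
#' @export
trial_rate_matrix <- function(rates, geom, provenance = list()) {
  stopifnot(is.matrix(rates), inherits(geom, "geometry"))
  if (ncol(rates) != geom$total_bins)
    stop("rates has ", ncol(rates), " columns but geometry has ",
         geom$total_bins, " bins")
  if (nrow(rates) < 1L) stop("need at least one trial")
  if (any(rates < 0, na.rm = TRUE))
    stop("firing rates must be non-negative")
  new_trial_rate_matrix(rates, geom, provenance)
}

# no non-negativity check: used for unclipped oracle output only
new_trial_rate_matrix <- function(rates, geom, provenance = list()) {
  structure(
    list(rates = rates, geometry = geom, n_trials = nrow(rates),
         provenance = provenance),
    class = "trial_rate_matrix"
  )
}

#' @export
print.trial_rate_matrix <- function(x, ...) {
  cat(sprintf("<trial_rate_matrix> %d trials x %d bins (%s)\n",
              x$n_trials, x$geometry$total_bins,
              if (x$geometry$dims == 1L) "1D" else
                paste(x$geometry$n_bins, collapse = " x ")))
  cat(sprintf("  mean rate %.3g Hz, peak %.3g Hz, %d missing bins\n",
              mean(x$rates, na.rm = TRUE), max(x$rates, na.rm = TRUE),
              sum(is.na(x$rates))))
  invisible(x)
}

#' Simulate trial-level firing-rate maps for one neuron
#'
#' Generates `n_trials` realisations of the place field described by
#' `params`. Per trial: the field is expressed with probability
#' `params$presence`; when expressed, its centre is displaced by a random
#' jitter offset (see `jitter_mode`) and the Gaussian peak term is evaluated
#' at every bin; the constant baseline and i.i.d. Gaussian noise
#' `N(0, noise_sd^2)` per bin are always added, whether or not the field is
#' expressed. Fields pushed across the track edge are simply truncated (no
#' wrap-around). Negative rates produced by the noise are clipped to zero by
#' default, since firing rates are physical quantities.
#'
#' @param params a [place_field_params()] object.
#' @param geom a [geometry()] object.
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   output. `NULL` uses the current RNG state.
#' @param clip clip negative rates at 0 (default `TRUE`). Disable only for
#'   numerical oracle checks.
#' @param jitter_mode `"positive"` draws each trial's centre offset uniformly
#'   from `[0, jitter_max]` (offsets in one direction, as the generative
#'   description states); `"symmetric"` draws from `[-jitter_max, jitter_max]`.
#' @param presence_rescale if `TRUE`, the peak amplitude on expressed trials
#'   is `peak / presence`, so the expected trial-averaged profile is invariant
#'   to the presence ratio and only trial-to-trial reliability changes. This
#'   is the condition under which field dropout degrades consistency without
#'   altering the average map; with `FALSE` (default) dropout also scales the
#'   average field.
#' @return A [trial_rate_matrix()]; `provenance` records params, seed, flags,
#'   and the per-trial presence/offset draws.
#' @examples
#' p <- place_field_params(peak = 10, mu = 25, sigma = 3, noise_sd = 0)
#' m <- simulate_trials(p, geometry(50), n_trials = 5, seed = 1)
#' @export
simulate_trials <- function(params, geom, n_trials, seed = NULL,
                            clip = TRUE,
                            jitter_mode = c("positive", "symmetric"),
                            presence_rescale = FALSE) {
  stopifnot(inherits(params, "place_field_params"), inherits(geom, "geometry"))
  jitter_mode <- match.arg(jitter_mode)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  check_mu_in_range(params, geom)
  if (!is.null(seed)) set.seed(as.integer(seed))

  B <- geom$total_bins
  # fixed draw order: presence, jitter offsets (per dimension), then noise
  present <- stats::runif(n_trials) < params$presence
  lo <- if (jitter_mode == "positive") 0 else -params$jitter_max
  offsets <- matrix(stats::runif(n_trials * geom$dims, lo, params$jitter_max),
                    nrow = n_trials)
  noise <- matrix(stats::rnorm(n_trials * B, 0, params$noise_sd),
                  nrow = n_trials)

  amp <- params$peak
  if (presence_rescale && params$presence > 0) amp <- amp / params$presence

  rates <- matrix(params$baseline, n_trials, B) + noise
  for (t in which(present)) {
    rates[t, ] <- rates[t, ] +
      gaussian_peak(amp, params$mu + offsets[t, ], params$sigma, geom)
  }
  if (clip) rates[rates < 0] <- 0

  maker <- if (clip) trial_rate_matrix else new_trial_rate_matrix
  maker(rates, geom, provenance = list(
    source = "simulation", params = unclass(params), seed = seed,
    clip = clip, jitter_mode = jitter_mode,
    presence_rescale = presence_rescale,
    present = present, offsets = offsets
  ))
}

#' Specification of a one-parameter population sweep
#'
#' Describes a population of simulated neurons in which one generative
#' parameter is swept over a range while all others are held at `fixed`.
#'
#' @param parameter one of `"peak"`, `"width"`, `"baseline"`, `"noise"`,
#'   `"jitter"`, `"presence"`.
#' @param low,high range bounds in the parameter's units (`low <= high`).
#' @param n_samples number of neurons (>= 1).
#' @param sampling `"evenly_spaced"` (both endpoints included; a single
#'   sample returns the low endpoint) or `"uniform_random"`.
#' @param fixed a [place_field_params()] giving the non-swept parameters.
#' @param n_trials trials per neuron.
#' @param seed integer master seed; per-neuron sub-seeds are derived from it
#'   by a counter scheme (see [sample_population()]).
#' @param presence_rescale passed to [simulate_trials()]; defaults to `TRUE`
#'   for presence sweeps so that dropout degrades reliability without
#'   rescaling the trial-averaged profile, `FALSE` otherwise.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(parameter, low, high, n_samples,
                       sampling = c("evenly_spaced", "uniform_random"),
                       fixed = place_field_params(),
                       n_trials = 30L, seed = 1L,
                       presence_rescale = identical(parameter, "presence")) {
  parameter <- match.arg(parameter, names(sweep_param_map()))
  sampling <- match.arg(sampling)
  stopifnot(inherits(fixed, "place_field_params"))
  if (!is.numeric(low) || !is.numeric(high) || low > high)
    stop("need low <= high")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1")
  structure(
    list(parameter = parameter, low = low, high = high,
         n_samples = n_samples, sampling = sampling, fixed = fixed,
         n_trials = as.integer(n_trials), seed = as.integer(seed),
         presence_rescale = isTRUE(presence_rescale)),
    class = "sweep_spec"
  )
}

sweep_param_map <- function() {
  c(peak = "peak", width = "sigma", baseline = "baseline",
    noise = "noise_sd", jitter = "jitter_max", presence = "presence")
}

# Counter-based sub-seed so any single neuron is reproducible in isolation.
neuron_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 1009 * as.numeric(i)) %% 2147483587)
}

#' Simulate a population along a parameter sweep
#'
#' Draws `n_samples` values of the swept parameter (evenly spaced over
#' `[low, high]` including both endpoints, or uniform random), builds the
#' per-neuron parameter set from `spec$fixed`, and simulates each neuron with
#' an independent sub-seed `(seed + 1009 * i) mod 2147483587` so that any
#' single neuron can be regenerated in isolation.
#'
#' @param spec a [sweep_spec()].
#' @param geom a [geometry()]; default 50-bin linear track with the field
#'   centred mid-track.
#' @return An object of class `"sim_population"`: a list with `values` (the
#'   swept values), `params` (list of [place_field_params()]), `matrices`
#'   (list of [trial_rate_matrix()]), `seeds`, and `spec`.
#' @export
sample_population <- function(spec, geom = geometry(50)) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(geom, "geometry"))
  field <- sweep_param_map()[[spec$parameter]]

  if (spec$sampling == "evenly_spaced") {
    values <- if (spec$n_samples == 1L) spec$low else
      seq(spec$low, spec$high, length.out = spec$n_samples)
  } else {
    set.seed(spec$seed)
    values <- stats::runif(spec$n_samples, spec$low, spec$high)
  }

  params <- vector("list", spec$n_samples)
  matrices <- vector("list", spec$n_samples)
  seeds <- integer(spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    p <- unclass(spec$fixed)
    p[[field]] <- values[i]
    p <- do.call(place_field_params, stats::setNames(
      p[c("peak", "mu", "sigma", "baseline", "noise_sd", "jitter_max",
          "presence")],
      c("peak", "mu", "sigma", "baseline", "noise_sd", "jitter_max",
        "presence")))
    seeds[i] <- neuron_seed(spec$seed, i)
    params[[i]] <- p
    matrices[[i]] <- simulate_trials(
      p, geom, spec$n_trials, seed = seeds[i],
      presence_rescale = spec$presence_rescale)
  }
  structure(
    list(values = values, params = params, matrices = matrices,
         seeds = seeds, spec = spec, geometry = geom),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d neurons, '%s' swept %s over [%g, %g], %d trials each\n",
    length(x$matrices), x$spec$parameter, x$spec$sampling,
    x$spec$low, x$spec$high, x$spec$n_trials))
  invisible(x)
}

#' Generate Poisson spike trains from per-trial expected rates
#'
#' Turns an expected trial-by-bin rate matrix into spike times under an
#' inhomogeneous Poisson process along a constant-speed traversal of the
#' track: each trial lasts `trial_duration_s`, the subject crosses the bins
#' at uniform speed, and within each bin spikes are drawn as a homogeneous
#' Poisson process at that bin's rate. Trials are laid out back-to-back in
#' session time. A synthetic position trace sampling every bin on every
#' trial is returned alongside, so the spike-level rate-map and permutation
#' machinery can be exercised end-to-end on data with known ground truth.
#'
#' Note: on a perfectly periodic trajectory (all trials the same duration) a
#' circular time shift is equivalent to a spatial rotation, to which both
#' tuning statistics are blind; supply varying per-trial durations when the
#' spikes are meant to exercise the circular-shift null.
#'
#' @param expected_rates trials x bins matrix of expected rates (Hz), or a
#'   [trial_rate_matrix()] (1D geometry only).
#' @param trial_duration_s duration of each trial, seconds (> 0); a scalar
#'   or one value per trial.
#' @param seed integer seed, or `NULL`.
#' @param samples_per_bin position-trace samples per bin per trial
#'   (default 4).
#' @return list with `spikes` (sorted spike times, s), `trace` (data.frame
#'   `time_s`, `position`, `trial`), `trial_windows` (data.frame `trial`,
#'   `t_start_s`, `t_end_s`) and `session_bounds` `c(0, total duration)`.
#' @export
synthesize_spikes <- function(expected_rates, trial_duration_s, seed = NULL,
                              samples_per_bin = 4L) {
  if (inherits(expected_rates, "trial_rate_matrix")) {
    if (expected_rates$geometry$dims != 1L)
      stop("spike synthesis is defined for 1D geometries")
    expected_rates <- expected_rates$rates
  }
  stopifnot(is.matrix(expected_rates))
  if (any(expected_rates < 0, na.rm = TRUE)) stop("rates must be >= 0")
  nt <- nrow(expected_rates); B <- ncol(expected_rates)
  if (!is.numeric(trial_duration_s) || any(trial_duration_s <= 0))
    stop("trial_duration_s must be positive")
  durs <- rep_len(trial_duration_s, nt)
  starts <- cumsum(c(0, durs[-nt]))
  if (!is.null(seed)) set.seed(as.integer(seed))

  spikes <- vector("list", nt)
  trace_parts <- vector("list", nt)
  ns <- samples_per_bin * B
  for (t in seq_len(nt)) {
    dt <- durs[t] / B
    r <- expected_rates[t, ]
    r[is.na(r)] <- 0
    counts <- stats::rpois(B, r * dt)
    if (sum(counts) > 0) {
      bin_idx <- rep.int(seq_len(B), counts)
      spikes[[t]] <- starts[t] + (bin_idx - 1) * dt +
        stats::runif(sum(counts)) * dt
    }
    trace_parts[[t]] <- data.frame(
      time_s = starts[t] + (seq_len(ns) - 0.5) / ns * durs[t],
      position = (seq_len(ns) - 0.5) / ns * B,   # track units = bins
      trial = t
    )
  }
  spikes <- sort(unlist(spikes, use.names = FALSE))
  windows <- data.frame(trial = seq_len(nt), t_start_s = starts,
                        t_end_s = starts + durs)
  list(spikes = if (length(spikes)) spikes else numeric(0),
       trace = do.call(rbind, trace_parts), trial_windows = windows,
       session_bounds = c(0, sum(durs)))
}
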