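#' Position trace of a session on a linear track
#'
#' Validates and packages tracking samples. Speed, when absent, is derived
#' by central differences of position over time (within each trial segment
#' when trial ids are given, so inter-trial jumps do not leak into speeds).
#'
#' @param times sample times, seconds, strictly increasing.
#' @param positions track coordinate of each sample (cm or virtual units),
#'   within `[0, n_bins * bin_width]`.
#' @param trial optional integer trial id per sample.
#' @param speed optional running speed per sample (units of position per s);
#'   derived if missing.
#' @return data.frame of class `"position_trace"` with columns `time_s`,
#'   `position`, `trial`, `speed`.
#' @export
position_trace <- function(times, positions, trial = NULL, speed = NULL) {
  if (length(times) == 0L) stop("empty trace")
  if (length(times) != length(positions))
    stop("times and positions must have the same length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(trial)) trial <- rep(1L, length(times))
  if (is.null(speed)) {
    speed <- numeric(length(times))
    for (tr in unique(trial)) {
      i <- which(trial == tr)
      speed[i] <- central_diff_speed(times[i], positions[i])
    }
  }
  out <- data.frame(time_s = times, position = positions,
                    trial = as.integer(trial), speed = speed)
  class(out) <- c("position_trace", "data.frame")
  out
}

central_diff_speed <- function(t, x) {
  n <- length(t)
  if (n == 1L) return(0)
  s <- numeric(n)
  if (n > 2L) s[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  s[1] <- (x[2] - x[1]) / (t[2] - t[1])
  s[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  abs(s)
}

# Seconds credited to each sample: the span between the midpoints to its
# neighbours. Segment boundaries default to half a gap beyond the end
# samples, so evenly spaced samples each get exactly one inter-sample
# interval; explicit bounds (e.g. trial windows) can be supplied.
sample_durations <- function(t, lo = NULL, hi = NULL) {
  n <- length(t)
  if (n == 1L) {
    if (is.null(lo) || is.null(hi)) return(0)
    return(hi - lo)
  }
  d <- diff(t)
  if (is.null(lo)) lo <- t[1] - d[1] / 2
  if (is.null(hi)) hi <- t[n] + d[n - 1] / 2
  mids <- c(lo, t[-n] + d / 2, hi)
  diff(mids)
}

position_to_bin <- function(pos, geom) {
  b <- floor(pos / geom$bin_width)
  # positions exactly at the track end fall in the last bin
  pmin(pmax(b, 0L), geom$total_bins - 1L)
}

#' Occupancy of spatial bins
#'
#' Accumulates time per bin from a position trace, excluding samples slower
#' than `min_speed`, and normalises to occupancy probabilities `p(x)`.
#'
#' @param trace a [position_trace()].
#' @param geom a 1D [geometry()].
#' @param min_speed samples with speed below this are excluded (default 0,
#'   i.e. no filtering; empirical pipelines commonly use 5 cm/s).
#' @return An object of class `"occupancy"`: list with `seconds` (time per
#'   bin, s) and `p` (occupancy probability, sums to 1 over bins with time).
#' @export
compute_occupancy <- function(trace, geom, min_speed = 0) {
  stopifnot(inherits(trace, "position_trace"), inherits(geom, "geometry"))
  if (geom$dims != 1L) stop("occupancy is defined for 1D geometries")
  secs <- numeric(geom$total_bins)
  for (tr in unique(trace$trial)) {
    seg <- trace[trace$trial == tr, ]
    dur <- sample_durations(seg$time_s)
    keep <- seg$speed >= min_speed
    if (!any(keep)) next
    bins <- position_to_bin(seg$position[keep], geom) + 1L
    secs <- secs + as.numeric(
      tapply(dur[keep], factor(bins, levels = seq_len(geom$total_bins)),
             sum, default = 0))
  }
  if (sum(secs) == 0) stop("empty occupancy: all samples filtered out")
  structure(list(seconds = secs, p = secs / sum(secs)), class = "occupancy")
}

#' Trial-by-bin rate map from spikes and positions
#'
#' The classic occupancy-normalised rate map, per trial:
#' `rate[t, x] = (spikes of trial t falling in bin x) / (seconds trial t
#' spent in bin x)`. Spike positions are linearly interpolated from the
#' trace at spike times. Bins a trial never occupied (at or above
#' `min_speed`) are `NA` — missing data, not zero rate. Spikes outside every
#' trial window, or landing in a zero-occupancy bin, are ignored; their
#' count is reported in the result's `dropped_spikes`.
#'
#' @param spikes sorted spike times, seconds.
#' @param trace a [position_trace()].
#' @param geom a 1D [geometry()].
#' @param trial_windows data.frame with columns `trial`, `t_start_s`,
#'   `t_end_s` (non-overlapping; spikes are assigned by
#'   `t_start_s <= t < t_end_s`).
#' @param min_speed occupancy speed filter (see [compute_occupancy()]); the
#'   same filter is applied to spikes via the speed at the nearest sample.
#' @return A [trial_rate_matrix()] with extra fields `occupancy_seconds`
#'   (trials x bins matrix), `spike_counts` (same shape) and
#'   `dropped_spikes`.
#' @export
spike_rate_matrix <- function(spikes, trace, geom, trial_windows,
                              min_speed = 0) {
  stopifnot(inherits(trace, "position_trace"), inherits(geom, "geometry"))
  if (geom$dims != 1L) stop("spike rate maps are built on 1D geometries")
  if (is.unsorted(spikes)) stop("spikes must be sorted")
  w <- trial_windows
  if (!all(c("trial", "t_start_s", "t_end_s") %in% names(w)))
    stop("trial_windows needs columns trial, t_start_s, t_end_s")
  o <- order(w$t_start_s)
  w <- w[o, ]
  if (any(w$t_end_s[-nrow(w)] > w$t_start_s[-1] + 1e-12))
    stop("trial windows must not overlap")

  nt <- nrow(w); B <- geom$total_bins
  occ <- counts <- matrix(0, nt, B)
  dropped <- 0L
  for (i in seq_len(nt)) {
    seg <- trace[trace$time_s >= w$t_start_s[i] & trace$time_s < w$t_end_s[i], ]
    if (nrow(seg) == 0L) {
      dropped <- dropped +
        sum(spikes >= w$t_start_s[i] & spikes < w$t_end_s[i])
      next
    }
    dur <- sample_durations(seg$time_s, lo = w$t_start_s[i], hi = w$t_end_s[i])
    keep <- seg$speed >= min_speed
    if (any(keep)) {
      bins <- position_to_bin(seg$position[keep], geom) + 1L
      occ[i, ] <- as.numeric(tapply(
        dur[keep], factor(bins, levels = seq_len(B)), sum, default = 0))
    }
    sp <- spikes[spikes >= w$t_start_s[i] & spikes < w$t_end_s[i]]
    if (length(sp) > 0L && any(keep)) {
      pos <- stats::approx(seg$time_s, seg$position, xout = sp, rule = 2)$y
      spd <- stats::approx(seg$time_s, seg$speed, xout = sp, rule = 2,
                           method = "constant", f = 0.5)$y
      ok <- spd >= min_speed
      dropped <- dropped + sum(!ok)
      sb <- position_to_bin(pos[ok], geom) + 1L
      counts[i, ] <- counts[i, ] + tabulate(sb, nbins = B)
    } else {
      dropped <- dropped + length(sp)
    }
  }
  n_outside <- length(spikes) -
    sum(vapply(seq_len(nt), function(i)
      sum(spikes >= w$t_start_s[i] & spikes < w$t_end_s[i]), integer(1)))
  dropped <- dropped + n_outside
  # spikes in never-occupied bins cannot be rated
  in_dead_bin <- counts > 0 & occ == 0
  dropped <- dropped + sum(counts[in_dead_bin])
  counts[in_dead_bin] <- 0

  rates <- counts / occ
  rates[occ == 0] <- NA_real_
  out <- trial_rate_matrix(rates, geom, provenance = list(
    source = "spikes", min_speed = min_speed))
  out$occupancy_seconds <- occ
  out$spike_counts <- counts
  out$dropped_spikes <- dropped
  if (dropped > 0L)
    message(dropped, " spike(s) outside trial windows or unrateable; ignored")
  out
}

#' Gaussian smoothing of rate maps
#'
#' Convolves each trial row with a Gaussian kernel of SD `kernel_sd_bins`
#' along the spatial axis (separably along both axes for grids), truncated
#' at 3 SD. At the track edges the kernel is renormalised so its weights sum
#' to 1 at every bin, which preserves flat maps exactly and each row's mean
#' to numerical precision.
#'
#' @param x a [trial_rate_matrix()], or a numeric matrix (trials x bins,
#'   treated as 1D), or a numeric vector (one map).
#' @param kernel_sd_bins Gaussian SD in bins; 0 returns the input unchanged.
#' @return same type as the input, smoothed.
#' @export
smooth_map <- function(x, kernel_sd_bins) {
  if (!is.numeric(kernel_sd_bins) || kernel_sd_bins < 0)
    stop("kernel_sd_bins must be >= 0")
  if (kernel_sd_bins == 0) return(x)
  if (inherits(x, "trial_rate_matrix")) {
    geom <- x$geometry
    if (geom$dims == 1L) {
      x$rates <- x$rates %*% t(smoothing_weights(ncol(x$rates), kernel_sd_bins))
    } else {
      n1 <- geom$n_bins[1]; n2 <- geom$n_bins[2]
      w1 <- smoothing_weights(n1, kernel_sd_bins)
      w2 <- smoothing_weights(n2, kernel_sd_bins)
      x$rates <- t(apply(x$rates, 1L, function(row) {
        g <- matrix(row, nrow = n2, ncol = n1)  # row-major flatten: y fastest
        as.vector(w2 %*% g %*% t(w1))
      }))
    }
    x$provenance$smoothed_sd <- kernel_sd_bins
    return(x)
  }
  if (is.matrix(x)) return(x %*% t(smoothing_weights(ncol(x), kernel_sd_bins)))
  as.vector(smoothing_weights(length(x), kernel_sd_bins) %*% x)
}

# B x B row-stochastic matrix: row j holds the edge-renormalised Gaussian
# kernel centred on bin j, truncated at 3 SD.
smoothing_weights <- function(B, sd) {
  K <- ceiling(3 * sd)
  offs <- -K:K
  k <- exp(-offs^2 / (2 * sd^2))
  W <- matrix(0, B, B)
  for (j in seq_len(B)) {
    idx <- j + offs
    ok <- idx >= 1L & idx <= B
    W[j, idx[ok]] <- k[ok] / sum(k[ok])
  }
  W
}

#' Re-bin a rate matrix to a coarser resolution
#'
#' Merges adjacent bins in groups of `ncol / new_n_bins` (which must be an
#' integer), averaging rates within each group. With equal per-bin occupancy
#' this conserves the per-trial rate-times-occupancy total exactly. For 2D
#' geometries the divisor is applied per dimension.
#'
#' @param x a [trial_rate_matrix()].
#' @param new_n_bins target bin count (scalar for 1D, length-2 for 2D); must
#'   divide the source bin count per dimension.
#' @return a [trial_rate_matrix()] on the coarser geometry.
#' @export
rebin_matrix <- function(x, new_n_bins) {
  stopifnot(inherits(x, "trial_rate_matrix"))
  geom <- x$geometry
  new_n_bins <- as.integer(new_n_bins)
  if (length(new_n_bins) != geom$dims)
    stop("new_n_bins must match the geometry's dimensionality")
  if (any(geom$n_bins %% new_n_bins != 0L))
    stop("variant bin count must be a divisor of the source bin count")
  if (geom$dims == 1L) {
    fac <- geom$n_bins %/% new_n_bins
    grp <- rep(seq_len(new_n_bins), each = fac)
    new_rates <- t(apply(x$rates, 1L, function(r)
      tapply(r, grp, mean)))
  } else {
    fac <- geom$n_bins %/% new_n_bins
    co <- bin_coords(geom)
    grp <- (co[, 1] %/% fac[1]) * new_n_bins[2] + (co[, 2] %/% fac[2]) + 1L
    new_rates <- t(apply(x$rates, 1L, function(r) tapply(r, grp, mean)))
  }
  new_geom <- geometry(new_n_bins,
                       bin_width = geom$bin_width * geom$n_bins[1] / new_n_bins[1])
  trial_rate_matrix(unname(new_rates), new_geom,
                    provenance = c(x$provenance, list(rebinned_from = geom$n_bins)))
}

#' Quality-control criteria for neurons and sessions
#'
#' Default values follow common empirical practice for linear-track
#' recordings: neurons with session mean rates outside `[0.2, 20]` Hz or
#' fewer than 50 spikes are dropped; sessions need at least 15 trials;
#' samples slower than 5 cm/s are excluded from occupancy; trials whose
#' duration deviates more than 2 SD from the session mean are excluded; and
#' neurons whose spike presence ratio is below 0.5 are dropped.
#'
#' @param min_rate_hz,max_rate_hz session mean firing-rate bounds, Hz.
#' @param min_spikes minimum total spike count.
#' @param min_trials minimum trial count.
#' @param min_speed_cms minimum running speed, cm/s.
#' @param max_duration_sd maximum allowed deviation of a trial's duration
#'   from the session mean, in SD units.
#' @param min_presence minimum spike presence ratio.
#' @return list of class `"qc_criteria"`.
#' @export
qc_criteria <- function(min_rate_hz = 0.2, max_rate_hz = 20, min_spikes = 50,
                        min_trials = 15, min_speed_cms = 5,
                        max_duration_sd = 2, min_presence = 0.5) {
  if (min_rate_hz >= max_rate_hz) stop("min_rate_hz must be < max_rate_hz")
  structure(list(min_rate_hz = min_rate_hz, max_rate_hz = max_rate_hz,
                 min_spikes = min_spikes, min_trials = min_trials,
                 min_speed_cms = min_speed_cms,
                 max_duration_sd = max_duration_sd,
                 min_presence = min_presence),
            class = "qc_criteria")
}

#' Apply quality-control rules to a neuron/session summary
#'
#' @param summary list (or one-row data.frame) with `mean_rate_hz`,
#'   `n_spikes`, `n_trials`, `trial_durations_s` (vector), `presence_ratio`.
#' @param criteria a [qc_criteria()] object.
#' @return list with `keep` (logical) and `violations` (character vector of
#'   rule names, empty when the neuron passes), plus `trials_excluded`
#'   (indices of trials violating the duration rule).
#' @export
qc_filter <- function(summary, criteria = qc_criteria()) {
  stopifnot(inherits(criteria, "qc_criteria"))
  v <- character(0)
  if (!is.null(summary$mean_rate_hz)) {
    if (summary$mean_rate_hz < criteria$min_rate_hz) v <- c(v, "min_rate")
    if (summary$mean_rate_hz > criteria$max_rate_hz) v <- c(v, "max_rate")
  }
  if (!is.null(summary$n_spikes) && summary$n_spikes < criteria$min_spikes)
    v <- c(v, "min_spikes")
  if (!is.null(summary$n_trials) && summary$n_trials < criteria$min_trials)
    v <- c(v, "min_trials")
  bad_trials <- integer(0)
  durs <- summary$trial_durations_s
  if (!is.null(durs) && length(durs) > 1L && stats::sd(durs) > 0) {
    z <- abs(durs - mean(durs)) / stats::sd(durs)
    bad_trials <- which(z > criteria$max_duration_sd)
    if (length(bad_trials) > 0L) v <- c(v, "max_duration_sd")
  }
  if (!is.null(summary$presence_ratio) &&
      summary$presence_ratio < criteria$min_presence)
    v <- c(v, "min_presence")
  list(keep = length(v) == 0L, violations = v, trials_excluded = bad_trials)
}

#' Mask edge bins of a rate matrix
#'
#' Optional post-hoc mask dropping the first and last `n_edge` bins of a 1D
#' map (commonly used near reward sites on linear tracks); masked bins
#' become `NA` so downstream metrics exclude them.
#'
#' @param x a [trial_rate_matrix()] (1D).
#' @param n_edge number of bins to mask at each end (default 3).
#' @return the matrix with edge bins set to `NA`.
#' @export
mask_edge_bins <- function(x, n_edge = 3L) {
  stopifnot(inherits(x, "trial_rate_matrix"), x$geometry$dims == 1L)
  B <- x$geometry$total_bins
  n_edge <- as.integer(n_edge)
  if (n_edge < 0L || 2L * n_edge >= B) stop("n_edge out of range")
  if (n_edge > 0L)
    x$rates[, c(seq_len(n_edge), (B - n_edge + 1L):B)] <- NA_real_
  x
}
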