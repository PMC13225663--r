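#' Circular-shift surrogate spike trains
#'
#' Produces null spike trains by rotating all spike times by a random offset
#' modulo the session length. This preserves the spike count, firing rate and
#' autocorrelation structure exactly (inter-spike intervals change only
#' across the wrap point) while destroying the relationship between spikes
#' and position. Offsets are drawn uniformly from
#' `[min_shift_s, T - min_shift_s]` so near-zero shifts that trivially
#' reproduce the observed statistic are excluded.
#'
#' @param spikes sorted spike times within `session_bounds`, seconds.
#' @param session_bounds length-2 vector `c(start, end)` of the session.
#' @param n number of surrogates.
#' @param seed integer seed, or `NULL`.
#' @param min_shift_s minimum shift magnitude, seconds (default 1).
#' @param offsets optional explicit offsets (length `n`), overriding the
#'   random draw — useful for deterministic checks.
#' @return list of `n` sorted surrogate spike-time vectors.
#' @export
circular_surrogates <- function(spikes, session_bounds, n, seed = NULL,
                                min_shift_s = 1, offsets = NULL) {
  b0 <- session_bounds[1]; b1 <- session_bounds[2]
  T_len <- b1 - b0
  if (length(spikes) && (any(spikes < b0) || any(spikes > b1)))
    stop("spikes must lie within session_bounds")
  if (is.null(offsets)) {
    if (T_len < 2 * min_shift_s)
      stop("session shorter than twice min_shift_s")
    if (!is.null(seed)) set.seed(as.integer(seed))
    offsets <- stats::runif(n, min_shift_s, T_len - min_shift_s)
  } else if (length(offsets) != n) {
    stop("offsets must have length n")
  }
  lapply(offsets, function(o) sort(((spikes - b0 + o) %% T_len) + b0))
}

# Random per-trial bin offsets for rate-level surrogates; one row per
# surrogate. Drawing is isolated here so the fast statistic path and the
# materialised-surrogate path consume identical random streams.
draw_row_offsets <- function(n_trials, n_surrogates, n_bins) {
  matrix(sample.int(n_bins, n_surrogates * n_trials, replace = TRUE) - 1L,
         nrow = n_surrogates)
}

#' Circular row-shift surrogates of a rate matrix
#'
#' The rate-level analogue of spike-train circular shifting, for simulated
#' trial-by-bin matrices that have no underlying spikes: each surrogate
#' circularly shifts every trial row by an independent random bin offset,
#' preserving each row's multiset of values (hence row sums, the grand mean
#' and the total sum of squares) while destroying across-trial spatial
#' alignment.
#'
#' @param x a [trial_rate_matrix()] or trials x bins matrix (>= 2 bins).
#' @param n number of surrogates.
#' @param seed integer seed, or `NULL`.
#' @return list of `n` surrogate matrices (plain matrices).
#' @export
rate_row_surrogates <- function(x, n, seed = NULL) {
  m <- if (inherits(x, "trial_rate_matrix")) x$rates else as.matrix(x)
  B <- ncol(m)
  if (B < 2L) stop("nothing to shift: need at least 2 bins")
  if (!is.null(seed)) set.seed(as.integer(seed))
  offs <- draw_row_offsets(nrow(m), n, B)
  lapply(seq_len(n), function(s) shift_rows(m, offs[s, ]))
}

shift_rows <- function(m, offsets) {
  B <- ncol(m)
  out <- m
  for (t in seq_len(nrow(m))) {
    o <- offsets[t] %% B
    if (o > 0L) out[t, ] <- m[t, c((B - o + 1L):B, seq_len(B - o))]
  }
  out
}

#' Null distributions of SI and F under row-shift surrogates
#'
#' Computes the spatial-information and ANOVA-F null values for `n`
#' circular row-shift surrogates of a complete rate matrix without
#' materialising the surrogates. Row shifts leave each row's values (hence
#' the grand mean and total sum of squares) untouched, so both statistics
#' depend on the surrogate only through its column means, which makes the
#' null cheap to evaluate. Results are identical to computing the metrics on
#' [rate_row_surrogates()] with the same seed.
#'
#' @param x a [trial_rate_matrix()] or complete (no `NA`) trials x bins
#'   matrix.
#' @param n number of surrogates (default 1000).
#' @param seed integer seed, or `NULL`.
#' @param occupancy occupancy probabilities for SI (default uniform).
#' @return list with two `"null_distribution"` objects, `si` and `f`; each
#'   has `values`, `n_surrogates`, `percentile_95` and `method`.
#' @export
permutation_null <- function(x, n = 1000L, seed = NULL, occupancy = NULL) {
  m <- if (inherits(x, "trial_rate_matrix")) x$rates else as.matrix(x)
  B <- ncol(m); Tn <- nrow(m)
  if (B < 2L) stop("nothing to shift: need at least 2 bins")
  if (anyNA(m)) {
    # unbalanced case: fall back to explicit surrogates
    surr <- rate_row_surrogates(m, n, seed)
    si_vals <- vapply(surr, function(s)
      as.numeric(spatial_information(tuning_curve(s, occupancy))), numeric(1))
    f_vals <- vapply(surr, function(s) anova_f(s)$f, numeric(1))
    return(list(si = null_distribution(si_vals, "rate_row_shift"),
                f = null_distribution(f_vals, "rate_row_shift")))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  offs <- draw_row_offsets(Tn, n, B)

  p <- if (is.null(occupancy)) rep(1 / B, B) else occupancy / sum(occupancy)
  N <- Tn * B
  grand <- mean(m)
  sst <- sum(m^2) - N * grand^2
  # column-permutation lookup: row o+1 = bin indices after a shift of o
  P <- t(vapply(0:(B - 1), function(o)
    c((B - o + 1L):B, seq_len(B - o))[seq_len(B)], integer(B)))
  P[1, ] <- seq_len(B)
  rows <- seq_len(Tn)

  si_vals <- f_vals <- numeric(n)
  for (s in seq_len(n)) {
    idx <- P[offs[s, ] + 1L, , drop = FALSE]       # T x B source columns
    cs <- .colSums(m[(idx - 1L) * Tn + rows], Tn, B)
    cm <- cs / Tn
    # SI
    gbar <- sum(p * cm)
    if (gbar > 0) {
      r <- cm / gbar
      pos <- r > 0
      si_vals[s] <- sum(p[pos] * r[pos] * log2(r[pos]))
    } else si_vals[s] <- NaN
    # F
    ssb <- Tn * sum((cm - grand)^2)
    ssw <- sst - ssb
    f_vals[s] <- if (ssw <= 0 && ssb <= 0) NaN else
      if (ssw <= 0) Inf else (ssb / (B - 1)) / (ssw / (N - B))
  }
  list(si = null_distribution(si_vals, "rate_row_shift"),
       f = null_distribution(f_vals, "rate_row_shift"))
}

null_distribution <- function(values, method) {
  structure(
    list(values = values, n_surrogates = length(values),
         percentile_95 = stats::quantile(values, 0.95, names = FALSE,
                                         na.rm = TRUE),
         method = method),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d surrogates (%s), 95th percentile %.4g\n",
              x$n_surrogates, x$method, x$percentile_95))
  invisible(x)
}

#' Percentile permutation test
#'
#' Declares significance when the observed statistic strictly exceeds the
#' 95th percentile of its surrogate null distribution (the conventional
#' permutation-corrected p < 0.05 rule; ties at the percentile are not
#' significant). The companion permutation p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n)` is reported alongside.
#'
#' @param observed observed statistic; `NaN` yields a non-significant result
#'   flagged `"undefined observed statistic"`.
#' @param null a `"null_distribution"` (from [permutation_null()] or built
#'   with surrogate values) or a numeric vector of null values.
#' @param alpha nominal level; the percentile used is `1 - alpha`
#'   (default 0.05).
#' @return list with `p`, `significant`, `critical` (the null percentile)
#'   and `flags`.
#' @export
permutation_test <- function(observed, null, alpha = 0.05) {
  vals <- if (inherits(null, "null_distribution")) null$values else
    as.numeric(null)
  if (length(vals) == 0L) stop("empty null distribution")
  crit <- stats::quantile(vals, 1 - alpha, names = FALSE, na.rm = TRUE)
  if (is.na(observed) || is.nan(observed)) {
    return(list(p = NA_real_, significant = FALSE, critical = crit,
                flags = "undefined observed statistic"))
  }
  p <- (1 + sum(vals >= observed, na.rm = TRUE)) / (1 + length(vals))
  list(p = p, significant = observed > crit, critical = crit,
       flags = character(0))
}

#' Dual-metric spatial-tuning test of one neuron
#'
#' Runs the full per-neuron detection pipeline on a trial-by-bin rate
#' matrix: observed spatial information and ANOVA F, circular row-shift
#' permutation nulls for both, percentile significance at `alpha`, the
#' fixed SI threshold rule, and the four-way classification for both
#' criterion pairings.
#'
#' @param x a [trial_rate_matrix()] or trials x bins matrix.
#' @param n_surrogates surrogates per null (default 1000).
#' @param seed integer seed for the surrogate draw.
#' @param alpha significance level of the percentile rule (default 0.05).
#' @param si_threshold fixed spatial-information cutoff, bits/spike
#'   (default 0.25).
#' @param occupancy occupancy probabilities for SI (default uniform).
#' @param keep_nulls retain the full null distributions in the result.
#' @return object of class `"tuning_test"`: `si`, `f_stat`, `p_si`, `p_f`,
#'   `sig_si_perm`, `sig_f_perm`, `sig_si_thresh`, `category_perm`
#'   (SI-perm vs F-perm), `category_thresh` (SI-threshold vs F-perm),
#'   `method`, and optionally `null_si`, `null_f`.
#' @export
test_spatial_tuning <- function(x, n_surrogates = 1000L, seed = NULL,
                                alpha = 0.05, si_threshold = 0.25,
                                occupancy = NULL, keep_nulls = FALSE) {
  si <- as.numeric(spatial_information(
    if (inherits(x, "trial_rate_matrix")) tuning_curve(x, occupancy)
    else tuning_curve(as.matrix(x), occupancy)))
  f <- anova_f(x)$f
  nulls <- permutation_null(x, n_surrogates, seed, occupancy)
  t_si <- permutation_test(si, nulls$si, alpha)
  t_f <- permutation_test(f, nulls$f, alpha)
  res <- list(
    si = si, f_stat = f,
    p_si = t_si$p, p_f = t_f$p,
    sig_si_perm = t_si$significant, sig_f_perm = t_f$significant,
    sig_si_thresh = !is.na(si) && si > si_threshold,
    si_threshold = si_threshold, alpha = alpha,
    n_surrogates = as.integer(n_surrogates),
    method = nulls$f$method, seed = seed
  )
  res$category_perm <- four_way(res$sig_si_perm, res$sig_f_perm)
  res$category_thresh <- four_way(res$sig_si_thresh, res$sig_f_perm)
  if (keep_nulls) { res$null_si <- nulls$si; res$null_f <- nulls$f }
  structure(res, class = "tuning_test")
}

four_way <- function(sig_si, sig_f) {
  if (is.na(sig_si) || is.na(sig_f)) stop("missing significance flag")
  if (sig_si && sig_f) "both" else if (sig_si) "si_only" else
    if (sig_f) "anova_only" else "neither"
}

#' @export
print.tuning_test <- function(x, ...) {
  cat("<tuning_test>\n")
  cat(sprintf("  SI = %.4g bits/spike (perm p = %.4g%s; threshold %g: %s)\n",
              x$si, x$p_si, if (x$sig_si_perm) ", significant" else "",
              x$si_threshold, if (x$sig_si_thresh) "above" else "below"))
  cat(sprintf("  F  = %.4g (perm p = %.4g%s)\n",
              x$f_stat, x$p_f, if (x$sig_f_perm) ", significant" else ""))
  cat(sprintf("  category: %s (perm/perm), %s (threshold/perm); %d surrogates, %s\n",
              x$category_perm, x$category_thresh, x$n_surrogates, x$method))
  invisible(x)
}

#' Run the detection pipeline over a population
#'
#' Applies [test_spatial_tuning()] to every neuron of a simulated population
#' (or list of rate matrices), with per-neuron surrogate seeds derived from
#' `seed` by the same counter scheme as [sample_population()].
#'
#' @param x a `"sim_population"` or a list of [trial_rate_matrix()] objects.
#' @param n_surrogates,alpha,si_threshold,occupancy passed to
#'   [test_spatial_tuning()].
#' @param seed master seed for surrogate draws.
#' @return data.frame with one row per neuron: `neuron_id`, `si`, `f_stat`,
#'   `p_si`, `p_f`, `sig_si_perm`, `sig_f_perm`, `sig_si_thresh`,
#'   `category_perm`, `category_thresh`.
#' @export
detect_population <- function(x, n_surrogates = 1000L, seed = 1L,
                              alpha = 0.05, si_threshold = 0.25,
                              occupancy = NULL) {
  mats <- if (inherits(x, "sim_population")) x$matrices else x
  rows <- lapply(seq_along(mats), function(i) {
    tt <- test_spatial_tuning(mats[[i]], n_surrogates,
                              seed = neuron_seed(seed, i),
                              alpha = alpha, si_threshold = si_threshold,
                              occupancy = occupancy)
    data.frame(neuron_id = i, si = tt$si, f_stat = tt$f_stat,
               p_si = tt$p_si, p_f = tt$p_f,
               sig_si_perm = tt$sig_si_perm, sig_f_perm = tt$sig_f_perm,
               sig_si_thresh = tt$sig_si_thresh,
               category_perm = tt$category_perm,
               category_thresh = tt$category_thresh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Four-way classification of a detected population
#'
#' Partitions neurons into `both`, `si_only`, `anova_only` and `neither`
#' under a chosen pairing of criteria: permutation-vs-permutation
#' (`"perm_perm"`) or SI-threshold-vs-ANOVA-permutation (`"thresh_perm"`).
#'
#' @param results data.frame from [detect_population()] (needs the relevant
#'   significance flag columns).
#' @param criterion_pair `"perm_perm"` or `"thresh_perm"`.
#' @return list with `categories` (character per neuron), `counts` (named
#'   integer vector over the four categories) and `proportions`.
#' @export
classify_cells <- function(results,
                           criterion_pair = c("perm_perm", "thresh_perm")) {
  criterion_pair <- match.arg(criterion_pair)
  si_col <- if (criterion_pair == "perm_perm") "sig_si_perm" else "sig_si_thresh"
  if (!all(c(si_col, "sig_f_perm") %in% names(results)))
    stop("results is missing significance flags")
  sig_si <- results[[si_col]]
  sig_f <- results[["sig_f_perm"]]
  if (anyNA(sig_si) || anyNA(sig_f)) stop("missing significance flag")
  cats <- mapply(four_way, sig_si, sig_f)
  lev <- c("both", "si_only", "anova_only", "neither")
  counts <- table(factor(cats, levels = lev))
  list(categories = cats,
       counts = stats::setNames(as.integer(counts), lev),
       proportions = stats::setNames(as.numeric(counts) / length(cats), lev))
}

#' Proportion of a flag as a function of a score
#'
#' Groups neurons into score bins (equal-count quantile bins by default) and
#' returns the mean of a boolean per bin: the construction behind
#' "proportion significant vs F" and method-agreement curves.
#'
#' @param scores numeric score per neuron.
#' @param flags logical per neuron, aligned with `scores`.
#' @param n_score_bins number of score bins (default 20).
#' @param scheme `"equal_count"` (quantile bins) or `"equal_width"`.
#' @return data.frame with `center` (mean score per bin), `proportion`, `n`.
#' @export
binned_proportion_curve <- function(scores, flags, n_score_bins = 20L,
                                    scheme = c("equal_count", "equal_width")) {
  scheme <- match.arg(scheme)
  if (length(scores) != length(flags)) stop("scores and flags must align")
  ok <- !is.na(scores) & !is.na(flags)
  scores <- scores[ok]; flags <- flags[ok]
  if (length(scores) < n_score_bins)
    stop("fewer neurons than score bins")
  if (scheme == "equal_count") {
    grp <- ceiling(rank(scores, ties.method = "first") * n_score_bins /
                     length(scores))
  } else {
    brk <- seq(min(scores), max(scores), length.out = n_score_bins + 1L)
    grp <- findInterval(scores, brk, rightmost.closed = TRUE)
  }
  agg_c <- tapply(scores, grp, mean)
  agg_p <- tapply(as.numeric(flags), grp, mean)
  agg_n <- tapply(flags, grp, length)
  data.frame(center = as.numeric(agg_c), proportion = as.numeric(agg_p),
             n = as.integer(agg_n))
}

#' Spike-level spatial-tuning test
#'
#' The spike-train version of the detection pipeline: rate maps are built
#' with [spike_rate_matrix()], the null comes from [circular_surrogates()]
#' of the session-wide spike train, and every surrogate map is rebuilt with
#' exactly the same binning, speed filtering and smoothing as the observed
#' map (like-for-like nulls).
#'
#' @param spikes sorted spike times, s.
#' @param trace a [position_trace()].
#' @param geom a 1D [geometry()].
#' @param trial_windows data.frame `trial`, `t_start_s`, `t_end_s`.
#' @param session_bounds length-2 session bounds, s.
#' @param n_surrogates surrogates (default 1000).
#' @param seed integer seed.
#' @param min_shift_s minimum circular shift, s (default 1).
#' @param smooth_sd_bins Gaussian smoothing SD applied to observed and
#'   surrogate maps alike (default 0, none).
#' @param min_speed occupancy speed filter.
#' @param alpha,si_threshold as in [test_spatial_tuning()].
#' @return a `"tuning_test"` object with `method = "spike_circular_shift"`.
#' @export
test_spatial_tuning_spikes <- function(spikes, trace, geom, trial_windows,
                                       session_bounds, n_surrogates = 1000L,
                                       seed = NULL, min_shift_s = 1,
                                       smooth_sd_bins = 0, min_speed = 0,
                                       alpha = 0.05, si_threshold = 0.25) {
  build <- function(sp) {
    m <- suppressMessages(
      spike_rate_matrix(sp, trace, geom, trial_windows, min_speed))
    if (smooth_sd_bins > 0) m <- smooth_map(m, smooth_sd_bins)
    m
  }
  obs <- build(spikes)
  occ_sec <- colSums(obs$occupancy_seconds)
  occ_p <- occ_sec / sum(occ_sec)
  si <- as.numeric(spatial_information(tuning_curve(obs, occ_p)))
  f <- anova_f(obs)$f

  surr <- circular_surrogates(spikes, session_bounds, n_surrogates, seed,
                              min_shift_s)
  si_vals <- f_vals <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    ms <- build(surr[[s]])
    si_vals[s] <- as.numeric(spatial_information(tuning_curve(ms, occ_p)))
    f_vals[s] <- anova_f(ms)$f
  }
  null_si <- null_distribution(si_vals, "spike_circular_shift")
  null_f <- null_distribution(f_vals, "spike_circular_shift")
  t_si <- permutation_test(si, null_si, alpha)
  t_f <- permutation_test(f, null_f, alpha)
  res <- list(
    si = si, f_stat = f, p_si = t_si$p, p_f = t_f$p,
    sig_si_perm = t_si$significant, sig_f_perm = t_f$significant,
    sig_si_thresh = !is.na(si) && si > si_threshold,
    si_threshold = si_threshold, alpha = alpha,
    n_surrogates = as.integer(n_surrogates),
    method = "spike_circular_shift", seed = seed,
    null_si = null_si, null_f = null_f
  )
  res$category_perm <- four_way(res$sig_si_perm, res$sig_f_perm)
  res$category_thresh <- four_way(res$sig_si_thresh, res$sig_f_perm)
  structure(res, class = "tuning_test")
}
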