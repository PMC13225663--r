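#' Detect place fields in a trial-averaged map
#'
#' A place field is a maximal run of contiguous bins whose mean rate exceeds
#' `rel_threshold` times the map's peak rate, at least `min_width_bins` bins
#' long. The threshold is relative to the raw peak of the trial-averaged map
#' (baseline is not subtracted).
#'
#' @param mean_map numeric vector, mean rate per bin (1D).
#' @param rel_threshold fraction of the peak rate (default 0.2).
#' @param min_width_bins minimum run length to count as a field (default 2).
#' @return data.frame with one row per field: `start_bin`, `end_bin`
#'   (0-based, inclusive), `width_bins`, `peak_bin`, `peak_rate_hz`.
#'   Zero rows when the map is flat, all-zero or has no qualifying run. The
#'   attribute `"supra_bins"` carries the total number of supra-threshold
#'   bins over all runs (the field-width feature) and `"field_bins"` the
#'   0-based bins belonging to accepted fields.
#' @examples
#' p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 0,
#'                         noise_sd = 0)
#' detect_fields(tuning_profile(p, geometry(50)))  # bins 20..30, width 11
#' @export
detect_fields <- function(mean_map, rel_threshold = 0.2, min_width_bins = 2L) {
  if (length(mean_map) == 0L) stop("empty map")
  if (any(mean_map < 0, na.rm = TRUE)) stop("rates must be non-negative")
  peak <- max(mean_map, na.rm = TRUE)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      width_bins = integer(0), peak_bin = integer(0),
                      peak_rate_hz = numeric(0))
  # all-zero and exactly flat maps carry no spatial modulation: no fields
  if (!is.finite(peak) || peak <= 0 ||
      peak == min(mean_map, na.rm = TRUE)) {
    attr(empty, "supra_bins") <- 0L
    attr(empty, "field_bins") <- integer(0)
    return(empty)
  }
  supra <- !is.na(mean_map) & mean_map > rel_threshold * peak
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fields <- empty
  field_bins <- integer(0)
  for (i in which(runs$values)) {
    if (runs$lengths[i] < min_width_bins) next
    s <- starts[i]; e <- ends[i]
    seg <- mean_map[s:e]
    pk <- s + which.max(seg) - 1L
    fields <- rbind(fields, data.frame(
      start_bin = s - 1L, end_bin = e - 1L, width_bins = e - s + 1L,
      peak_bin = pk - 1L, peak_rate_hz = mean_map[pk]))
    field_bins <- c(field_bins, (s:e) - 1L)
  }
  attr(fields, "supra_bins") <- sum(supra)
  attr(fields, "field_bins") <- field_bins
  fields
}

#' Eight place-field features of a neuron
#'
#' Estimates the per-neuron feature vector used to characterise place-field
#' structure and trial-level reliability:
#' \describe{
#'   \item{peak_rate}{maximum of the trial-averaged map, Hz.}
#'   \item{avg_rate}{mean rate over all bins and trials, Hz.}
#'   \item{peak_to_avg}{tuning sharpness, `peak_rate / avg_rate`.}
#'   \item{field_width}{total number of bins above `rel_threshold` of the
#'     peak (all supra-threshold runs).}
#'   \item{n_fields}{number of distinct contiguous supra-threshold regions
#'     at least `min_width_bins` wide.}
#'   \item{field_consistency}{fraction of trials whose per-trial peak bin
#'     lies within `consistency_window` bins of the overall peak bin
#'     (per-trial ties broken toward the lowest bin index).}
#'   \item{presence_ratio}{fraction of trials with strictly positive rate in
#'     at least one bin of the detected field region; `NaN` when no field
#'     was detected.}
#'   \item{even_odd_r}{Pearson correlation between the mean maps of
#'     odd-numbered and even-numbered trials (the first trial is trial 1,
#'     odd); `NaN` when either half-map is constant.}
#' }
#' Computed on unsmoothed maps; smoothing, if wanted, is an explicit
#' upstream choice.
#'
#' @param x a [trial_rate_matrix()] or trials x bins matrix with >= 2 trials
#'   (1D feature definitions; 2D matrices are analysed by the tuning metrics
#'   only).
#' @param rel_threshold,min_width_bins field detection settings, see
#'   [detect_fields()].
#' @param consistency_window half-width of the peak-consistency window,
#'   bins (default 3).
#' @return named numeric vector of the 8 features, with attribute `"flags"`
#'   naming any degenerate cases.
#' @export
estimate_features <- function(x, rel_threshold = 0.2, min_width_bins = 2L,
                              consistency_window = 3L) {
  m <- if (inherits(x, "trial_rate_matrix")) x$rates else as.matrix(x)
  if (inherits(x, "trial_rate_matrix") && x$geometry$dims != 1L)
    stop("feature estimation is defined for 1D rate matrices")
  if (nrow(m) < 2L) stop("need at least 2 trials")
  flags <- character(0)

  mean_map <- colMeans(m, na.rm = TRUE)
  peak_rate <- max(mean_map, na.rm = TRUE)
  avg_rate <- mean(m, na.rm = TRUE)
  peak_to_avg <- if (avg_rate > 0) peak_rate / avg_rate else NaN

  fields <- detect_fields(mean_map, rel_threshold, min_width_bins)
  field_width <- attr(fields, "supra_bins")
  n_fields <- nrow(fields)
  field_bins <- attr(fields, "field_bins")

  # per-trial peak bin, ties broken toward the lowest index
  overall_peak_bin <- which.max(mean_map)
  trial_peaks <- apply(m, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  field_consistency <- mean(
    abs(trial_peaks - overall_peak_bin) <= consistency_window, na.rm = TRUE)

  if (length(field_bins) > 0L) {
    fb <- field_bins + 1L
    presence_ratio <- mean(apply(m[, fb, drop = FALSE], 1L, function(r)
      any(r > 0, na.rm = TRUE)))
  } else {
    presence_ratio <- NaN
    flags <- c(flags, "no detected field")
  }

  odd <- seq(1L, nrow(m), by = 2L)
  even <- seq(2L, nrow(m), by = 2L)
  map_odd <- colMeans(m[odd, , drop = FALSE], na.rm = TRUE)
  map_even <- colMeans(m[even, , drop = FALSE], na.rm = TRUE)
  ok <- is.finite(map_odd) & is.finite(map_even)
  if (sum(ok) > 1L && stats::sd(map_odd[ok]) > 0 &&
      stats::sd(map_even[ok]) > 0) {
    even_odd_r <- stats::cor(map_odd[ok], map_even[ok])
  } else {
    even_odd_r <- NaN
    flags <- c(flags, "constant even/odd map")
  }

  out <- c(peak_rate = peak_rate, avg_rate = avg_rate,
           peak_to_avg = peak_to_avg, field_width = as.numeric(field_width),
           n_fields = as.numeric(n_fields),
           field_consistency = field_consistency,
           presence_ratio = presence_ratio, even_odd_r = even_odd_r)
  attr(out, "flags") <- flags
  out
}

#' Feature matrix of a population
#'
#' Applies [estimate_features()] to every neuron and stacks the results.
#'
#' @param x a `"sim_population"` or list of rate matrices.
#' @param ... passed to [estimate_features()].
#' @return data.frame: `neuron_id` plus the 8 feature columns.
#' @export
feature_matrix <- function(x, ...) {
  mats <- if (inherits(x, "sim_population")) x$matrices else x
  rows <- lapply(seq_along(mats), function(i) {
    fv <- estimate_features(mats[[i]], ...)
    cbind(data.frame(neuron_id = i), as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
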