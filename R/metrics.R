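#' Trial-averaged tuning curve with occupancy
#'
#' Collapses a trial-by-bin rate matrix to its across-trial mean map and
#' attaches the occupancy probabilities used to weight the spatial
#' information score. For simulated matrices occupancy is uniform over the
#' bins; for empirical maps pass the session's occupancy. Bins with `NA`
#' rates in every trial (never occupied) are excluded from the curve and the
#' occupancy is renormalised over the remaining bins.
#'
#' @param x a [trial_rate_matrix()] or a plain trials x bins matrix.
#' @param occupancy optional vector of occupancy probabilities per bin
#'   (will be renormalised to sum to 1 over included bins); default uniform.
#' @return An object of class `"tuning_curve"`: list with `rate` (mean Hz per
#'   included bin), `p` (occupancy probability), `bins` (0-based indices of
#'   included bins), `overall_mean` (occupancy-weighted mean rate).
#' @export
tuning_curve <- function(x, occupancy = NULL) {
  rates <- if (inherits(x, "trial_rate_matrix")) x$rates else as.matrix(x)
  gamma <- colMeans(rates, na.rm = TRUE)
  keep <- !is.nan(gamma)
  gamma <- gamma[keep]
  if (is.null(occupancy)) {
    p <- rep(1 / sum(keep), sum(keep))
  } else {
    if (length(occupancy) != length(keep))
      stop("occupancy length must equal the number of bins")
    p <- occupancy[keep]
    if (any(p < 0)) stop("occupancy probabilities must be >= 0")
    if (sum(p) <= 0) stop("occupancy sums to zero")
    p <- p / sum(p)
  }
  structure(
    list(rate = gamma, p = p, bins = which(keep) - 1L,
         overall_mean = sum(p * gamma)),
    class = "tuning_curve"
  )
}

#' Skaggs spatial information (bits/spike)
#'
#' The information a single spike carries about position:
#' `SI = sum_x p(x) * (g(x)/gbar) * log2(g(x)/gbar)` where `p(x)` is the
#' occupancy probability of bin `x`, `g(x)` the mean firing rate in that bin
#' and `gbar = sum_x p(x) g(x)` the occupancy-weighted overall mean rate.
#' Bins with zero rate contribute 0 (the `x log x -> 0` limit). A completely
#' silent neuron (`gbar = 0`) yields `NaN` with the flag
#' `"silent neuron"`.
#'
#' SI is computed from the trial-averaged map, so it is insensitive to
#' trial-to-trial variability; it is invariant to scaling all rates by a
#' positive constant and strictly decreased by adding a constant baseline to
#' any non-flat curve.
#'
#' @param x a `"tuning_curve"`, a [trial_rate_matrix()], or a numeric vector
#'   of mean rates per bin.
#' @param occupancy occupancy probabilities (ignored when `x` is already a
#'   tuning curve); default uniform.
#' @return numeric scalar, bits/spike; `NaN` (with attribute `flag`) for a
#'   silent neuron.
#' @examples
#' spatial_information(c(4, 0, 0, 0))  # single active bin of 4 -> log2(4) = 2
#' spatial_information(rep(3, 10))     # flat map -> 0
#' @export
spatial_information <- function(x, occupancy = NULL) {
  if (inherits(x, "trial_rate_matrix")) {
    x <- tuning_curve(x, occupancy)
  } else if (!inherits(x, "tuning_curve")) {
    x <- tuning_curve(rbind(x), occupancy)
  }
  g <- x$rate
  if (any(g < 0)) stop("firing rates must be non-negative")
  gbar <- x$overall_mean
  if (gbar == 0) {
    si <- NaN
    attr(si, "flag") <- "silent neuron"
    return(si)
  }
  r <- g / gbar
  pos <- r > 0
  sum(x$p[pos] * r[pos] * log2(r[pos]))
}

#' One-way ANOVA F-statistic over spatial bins
#'
#' Treats spatial bins as groups and per-trial rates within a bin as the
#' observations, and returns the standard between/within variance ratio
#' `F = MS_between / MS_within`. High values mean firing differs across
#' positions consistently over trials. `NA` entries (unoccupied bins on some
#' trials) are dropped, giving an unbalanced one-way layout handled through
#' per-group counts. The statistic is invariant to adding a constant to, or
#' rescaling, all rates.
#'
#' Degenerate inputs are flagged rather than silently propagated:
#' zero within-group variance with structure between groups gives `Inf`
#' (`"degenerate: zero within-variance"`); a constant matrix gives `NaN`
#' (`"constant matrix"`).
#'
#' @param x a [trial_rate_matrix()] or a trials x bins numeric matrix
#'   (>= 2 bins with data, >= 2 observations somewhere).
#' @return list with `f` (the statistic), `df_between`, `df_within`, and
#'   `flags` (character vector, empty when the case is regular).
#' @examples
#' m <- cbind(c(1, 2, 3), c(4, 5, 6))
#' anova_f(m)$f  # 13.5
#' @export
anova_f <- function(x) {
  m <- if (inherits(x, "trial_rate_matrix")) x$rates else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 bins")
  n_j <- colSums(!is.na(m))
  use <- n_j > 0L
  if (sum(use) < 2L) stop("need data in at least 2 bins")
  m <- m[, use, drop = FALSE]
  n_j <- n_j[use]
  N <- sum(n_j)
  k <- ncol(m)
  if (N - k < 1L) stop("need at least 2 observations in some bin")

  means <- colMeans(m, na.rm = TRUE)
  grand <- sum(n_j * means) / N
  ss_between <- sum(n_j * (means - grand)^2)
  ss_within <- sum(sweep(m, 2L, means)^2, na.rm = TRUE)
  df_b <- k - 1L
  df_w <- N - k

  flags <- character(0)
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0 && ms_b == 0) {
    f <- NaN
    flags <- "constant matrix"
  } else if (ms_w == 0) {
    f <- Inf
    flags <- "degenerate: zero within-variance"
  } else {
    f <- ms_b / ms_w
  }
  list(f = f, df_between = df_b, df_within = df_w, flags = flags)
}
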