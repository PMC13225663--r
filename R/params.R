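#' Ground-truth parameters of a simulated place field
#'
#' Bundles the generative parameters of one simulated neuron: a Gaussian
#' firing-rate bump of amplitude `peak` (Hz) centred at `mu` (bin coordinates)
#' with spatial spread `sigma` (bins), riding on a constant baseline
#' `baseline` (Hz), with i.i.d. Gaussian rate noise of SD `noise_sd` (Hz)
#' added per bin on every trial. Trial-to-trial unreliability comes from
#' `jitter_max` (each trial's field centre is offset by a random amount up to
#' `jitter_max` bins) and `presence` (probability that the field is expressed
#' at all on a given trial).
#'
#' @param peak peak firing-rate amplitude A, Hz (>= 0).
#' @param mu field centre in 0-based bin coordinates; a scalar on a linear
#'   track or length-2 vector on a grid.
#' @param sigma field width (Gaussian SD), bins (> 0).
#' @param baseline constant background rate B0, Hz (>= 0).
#' @param noise_sd SD of the additive per-bin rate noise, Hz (>= 0).
#' @param jitter_max maximum per-trial field-centre offset, bins (>= 0).
#' @param presence probability that the field is expressed on a trial, in
#'   [0, 1].
#' @return An object of class `"place_field_params"`.
#' @seealso [tuning_profile()], [simulate_trials()]
#' @examples
#' place_field_params(peak = 10, mu = 25, sigma = 3)
#' @export
place_field_params <- function(peak = 10, mu = 25, sigma = 5, baseline = 1,
                               noise_sd = 1, jitter_max = 0, presence = 1) {
  p <- list(peak = peak, mu = mu, sigma = sigma, baseline = baseline,
            noise_sd = noise_sd, jitter_max = jitter_max, presence = presence)
  validate_params(p)
  structure(p, class = "place_field_params")
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$peak) && p$peak >= 0, "peak must be a non-negative scalar")
  chk(is.numeric(p$mu) && length(p$mu) %in% c(1L, 2L) && all(is.finite(p$mu)),
      "mu must be a numeric scalar (1D) or length-2 vector (2D)")
  chk(num1(p$sigma) && p$sigma > 0, "sigma must be positive")
  chk(num1(p$baseline) && p$baseline >= 0, "baseline must be non-negative")
  chk(num1(p$noise_sd) && p$noise_sd >= 0, "noise_sd must be non-negative")
  chk(num1(p$jitter_max) && p$jitter_max >= 0, "jitter_max must be non-negative")
  chk(num1(p$presence) && p$presence >= 0 && p$presence <= 1,
      "presence must lie in [0, 1]")
  invisible(p)
}

#' @export
print.place_field_params <- function(x, ...) {
  cat("<place_field_params>\n")
  cat(sprintf("  peak %g Hz at mu = %s, sigma %g bins\n",
              x$peak, paste(x$mu, collapse = ","), x$sigma))
  cat(sprintf("  baseline %g Hz, noise SD %g Hz, jitter <= %g bins, presence %g\n",
              x$baseline, x$noise_sd, x$jitter_max, x$presence))
  invisible(x)
}

check_mu_in_range <- function(params, geom) {
  mu <- params$mu
  if (length(mu) != geom$dims)
    stop("center out of range: mu has length ", length(mu),
         " but geometry has ", geom$dims, " dimension(s)")
  hi <- geom$n_bins - 1
  if (any(mu < 0) || any(mu > hi))
    stop("center out of range: mu must lie within [0, n_bins - 1]")
  invisible(TRUE)
}
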