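#' Run a parameter sweep and score every neuron
#'
#' Simulates the population described by `spec`, computes spatial
#' information and the ANOVA F for each neuron, and aggregates mean curves
#' over the swept values. This is the machinery behind the
#' metric-vs-parameter curves: sweep one generative parameter, hold the rest
#' fixed, and watch how each detection statistic responds.
#'
#' @param spec a [sweep_spec()].
#' @param geom a [geometry()] (default 50-bin track).
#' @param compute_features also estimate the 8 place-field features per
#'   neuron (1D only; default `FALSE`).
#' @param occupancy occupancy probabilities for SI (default uniform).
#' @return object of class `"sweep_result"`: `long` (one row per neuron:
#'   `parameter`, `swept_value`, `neuron_id`, `si`, `f_stat`, features if
#'   requested, `seed`), `summary` (per swept value: mean and SD of each
#'   metric), `argmax` (swept value maximising each metric's mean), and
#'   `spec`.
#' @export
run_sweep <- function(spec, geom = geometry(50), compute_features = FALSE,
                      occupancy = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  pop <- sample_population(spec, geom)
  n <- length(pop$matrices)
  si <- f <- numeric(n)
  for (i in seq_len(n)) {
    si[i] <- as.numeric(spatial_information(
      tuning_curve(pop$matrices[[i]], occupancy)))
    f[i] <- anova_f(pop$matrices[[i]])$f
  }
  long <- data.frame(parameter = spec$parameter, swept_value = pop$values,
                     neuron_id = seq_len(n), si = si, f_stat = f,
                     seed = pop$seeds, stringsAsFactors = FALSE)
  if (compute_features) {
    feat <- feature_matrix(pop)
    long <- cbind(long, feat[, setdiff(names(feat), "neuron_id")])
  }

  vals <- sort(unique(long$swept_value))
  summarise <- function(col) {
    data.frame(
      swept_value = vals,
      mean = as.numeric(tapply(long[[col]], long$swept_value, mean)),
      sd = as.numeric(tapply(long[[col]], long$swept_value, stats::sd))
    )
  }
  s_si <- summarise("si"); s_f <- summarise("f_stat")
  summary <- data.frame(swept_value = vals,
                        si_mean = s_si$mean, si_sd = s_si$sd,
                        f_mean = s_f$mean, f_sd = s_f$sd)
  argmax <- c(si = vals[which.max(summary$si_mean)],
              f = vals[which.max(summary$f_mean)])
  structure(
    list(long = long, summary = summary, argmax = argmax,
         spec = spec, geometry = geom),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> '%s' over [%g, %g], %d neurons\n",
              x$spec$parameter, x$spec$low, x$spec$high, nrow(x$long)))
  cat(sprintf("  mean SI maximal at %s = %g; mean F maximal at %s = %g\n",
              x$spec$parameter, x$argmax["si"],
              x$spec$parameter, x$argmax["f"]))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  s <- x$summary
  old <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(old))
  graphics::plot(s$swept_value, s$si_mean, type = "l", col = "red3", lwd = 2,
                 xlab = x$spec$parameter, ylab = "spatial information (bits/spike)",
                 ...)
  graphics::par(new = TRUE)
  graphics::plot(s$swept_value, s$f_mean, type = "l", col = "blue3", lwd = 2,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue3")
  graphics::mtext("ANOVA F", side = 4, line = 2.5, col = "blue3")
  graphics::legend("topright", legend = c("SI", "F"), lwd = 2,
                   col = c("red3", "blue3"), bty = "n")
  invisible(x)
}

#' Binning / smoothing sensitivity analysis
#'
#' Re-analyses the same simulated neurons under rate-map construction
#' variants — coarser binnings (which must divide the source bin count) and
#' Gaussian smoothing — and returns the paired per-neuron metrics, the basis
#' for sign tests of how construction choices move each statistic.
#'
#' @param population a `"sim_population"` (generate it at the finest
#'   resolution of interest) or list of [trial_rate_matrix()] objects.
#' @param variants list of variants; each a list with optional `n_bins`
#'   (target binning) and `smooth_sd` (kernel SD in bins, applied after any
#'   rebinning). An empty variant is the identity.
#' @param include_baseline prepend the untouched maps as variant
#'   `"baseline"` (default `TRUE`).
#' @return data.frame: `variant`, `n_bins`, `smooth_sd`, `neuron_id`, `si`,
#'   `f_stat` — one row per neuron per variant.
#' @export
run_sensitivity <- function(population, variants, include_baseline = TRUE) {
  mats <- if (inherits(population, "sim_population")) population$matrices
          else population
  if (length(mats) == 0L) stop("empty population")
  src_bins <- mats[[1]]$geometry$n_bins

  score <- function(mats, label, n_bins, smooth_sd) {
    si <- vapply(mats, function(m)
      as.numeric(spatial_information(tuning_curve(m))), numeric(1))
    f <- vapply(mats, function(m) anova_f(m)$f, numeric(1))
    data.frame(variant = label, n_bins = paste(n_bins, collapse = "x"),
               smooth_sd = smooth_sd, neuron_id = seq_along(mats),
               si = si, f_stat = f, stringsAsFactors = FALSE)
  }

  out <- list()
  if (include_baseline)
    out[["baseline"]] <- score(mats, "baseline", src_bins, 0)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    nb <- if (is.null(v$n_bins)) src_bins else as.integer(v$n_bins)
    sm <- if (is.null(v$smooth_sd)) 0 else v$smooth_sd
    label <- if (!is.null(names(variants)) && nzchar(names(variants)[i]))
      names(variants)[i] else
      sprintf("bins%s_sm%g", paste(nb, collapse = "x"), sm)
    vm <- mats
    if (!identical(nb, src_bins))
      vm <- lapply(vm, rebin_matrix, new_n_bins = nb)
    if (sm > 0) vm <- lapply(vm, smooth_map, kernel_sd_bins = sm)
    out[[label]] <- score(vm, label, nb, sm)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
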