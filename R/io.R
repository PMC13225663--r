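#' @name spatialtuning-io
#' @title Tab-separated serialization of simulations and results
#' @description All tables are plain TSV with a header row; `NaN`/`NA` are
#'   written as empty fields. JSON sidecars carry run metadata (geometry,
#'   parameters, seeds, package version).
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a simulated population to TSV
#'
#' Two files: a per-neuron parameter table (columns `neuron_id`, `A`, `mu`,
#' `sigma`, `B0`, `noise_sd`, `jitter_max`, `presence`, `seed`) and a long
#' rates table (`neuron_id`, `trial`, `bin`, `rate_hz`; bins 0-based).
#'
#' @param pop a `"sim_population"`.
#' @param params_path,rates_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_population_tsv <- function(pop, params_path, rates_path) {
  stopifnot(inherits(pop, "sim_population"))
  params <- do.call(rbind, lapply(seq_along(pop$params), function(i) {
    p <- pop$params[[i]]
    data.frame(neuron_id = i, A = p$peak, mu = paste(p$mu, collapse = ","),
               sigma = p$sigma, B0 = p$baseline, noise_sd = p$noise_sd,
               jitter_max = p$jitter_max, presence = p$presence,
               seed = pop$seeds[i])
  }))
  write_tsv(params, params_path)
  rates <- do.call(rbind, lapply(seq_along(pop$matrices), function(i) {
    m <- pop$matrices[[i]]$rates
    data.frame(neuron_id = i,
               trial = rep(seq_len(nrow(m)), times = ncol(m)),
               bin = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               rate_hz = as.vector(m))
  }))
  write_tsv(rates, rates_path)
  invisible(c(params_path, rates_path))
}

#' Read a long rates table back into rate matrices
#'
#' @param rates_path TSV with columns `neuron_id`, `trial`, `bin`,
#'   `rate_hz` (bins 0-based).
#' @param geom the [geometry()] the rates live on.
#' @return list of [trial_rate_matrix()] objects, in neuron_id order.
#' @export
read_rates_tsv <- function(rates_path, geom) {
  df <- read_tsv(rates_path)
  need <- c("neuron_id", "trial", "bin", "rate_hz")
  if (!all(need %in% names(df)))
    stop("rates TSV needs columns ", paste(need, collapse = ", "))
  lapply(split(df, df$neuron_id), function(d) {
    nt <- max(d$trial)
    m <- matrix(NA_real_, nt, geom$total_bins)
    m[cbind(d$trial, d$bin + 1L)] <- d$rate_hz
    trial_rate_matrix(m, geom, provenance = list(source = rates_path))
  })
}

#' Write spike trains and positions to TSV
#'
#' Spikes: columns `neuron_id`, `spike_time_s`. Positions: `time_s`,
#' `position`, `trial`.
#'
#' @param spikes list of spike-time vectors (one per neuron) or a single
#'   vector.
#' @param trace a [position_trace()] or data.frame.
#' @param spikes_path,positions_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_spikes_tsv <- function(spikes, trace, spikes_path, positions_path) {
  if (!is.list(spikes)) spikes <- list(spikes)
  sp <- do.call(rbind, lapply(seq_along(spikes), function(i)
    if (length(spikes[[i]]) == 0L) NULL else
      data.frame(neuron_id = i, spike_time_s = spikes[[i]])))
  if (is.null(sp))
    sp <- data.frame(neuron_id = integer(0), spike_time_s = numeric(0))
  write_tsv(sp, spikes_path)
  write_tsv(as.data.frame(trace)[, c("time_s", "position", "trial")],
            positions_path)
  invisible(c(spikes_path, positions_path))
}

#' Write a JSON run manifest
#'
#' Every CLI output directory carries one of these: the effective config,
#' seeds, package version and per-stage row counts, so a run can be
#' reproduced byte-for-byte.
#'
#' @param manifest named list.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package <- "spatialtuning"
  manifest$package_version <- as.character(utils::packageVersion("spatialtuning"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
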