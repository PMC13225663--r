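# Independent oracles and small fixture builders used across the suite.

# Textbook one-way ANOVA on a trials x bins matrix via the linear-model
# route, anova(lm(rate ~ bin)) (independent of the package's direct
# decomposition; unlike oneway.test it accepts singleton groups).
oneway_f_oracle <- function(m) {
  df <- data.frame(rate = as.vector(m),
                   bin = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  df <- df[!is.na(df$rate), ]
  df$bin <- droplevels(df$bin)
  stats::anova(stats::lm(rate ~ bin, data = df))[["F value"]][1]
}

# Brute-force PCA: explicit covariance eigendecomposition of the (optionally
# z-scored) matrix.
pca_oracle <- function(X, standardize = TRUE) {
  Xs <- scale(X, center = TRUE, scale = standardize)
  e <- eigen(stats::cov(Xs), symmetric = TRUE)
  list(loadings = e$vectors,
       scores = Xs %*% e$vectors,
       var_ratio = e$values / sum(e$values))
}

# 99% binomial interval around proportion p0 with n trials.
binom99 <- function(p0, n) {
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}

# Hand-evaluated Skaggs information for a curve and occupancy.
si_oracle <- function(rates, p) {
  p <- p / sum(p)
  gbar <- sum(p * rates)
  terms <- ifelse(rates > 0, p * (rates / gbar) * log2(rates / gbar), 0)
  sum(terms)
}

# One simulated neuron at the package's default study conditions.
default_matrix <- function(seed = 1, n_trials = 30, ...) {
  p <- place_field_params(...)
  simulate_trials(p, geometry(50), n_trials, seed = seed)
}

# Evenly covered constant-speed trace over a 50-bin track (one trial).
uniform_trace <- function(n_bins = 50, samples_per_bin = 4,
                          duration = 50, trial = 1L, t0 = 0) {
  ns <- n_bins * samples_per_bin
  position_trace(
    times = t0 + (seq_len(ns) - 0.5) / ns * duration,
    positions = (seq_len(ns) - 0.5) / ns * n_bins,
    trial = rep(trial, ns)
  )
}
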