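test_that("uniform constant-speed coverage gives uniform occupancy", {
  tr <- uniform_trace()
  occ <- compute_occupancy(tr, geometry(50))
  expect_equal(occ$p, rep(1 / 50, 50), tolerance = 1e-12)
  expect_equal(sum(occ$p), 1, tolerance = 1e-12)
  expect_equal(sum(occ$seconds), 50, tolerance = 1e-9)
})

test_that("slow samples contribute no occupancy and full filtering errors", {
  n <- 100
  tr <- position_trace(times = seq(0.5, 99.5, by = 1),
                       positions = rep(seq(0.5, 49.5, by = 1), 2),
                       speed = rep(c(0, 10), each = 50))
  occ_all <- compute_occupancy(tr, geometry(50), min_speed = 0)
  occ_fast <- compute_occupancy(tr, geometry(50), min_speed = 5)
  expect_lt(sum(occ_fast$seconds), sum(occ_all$seconds))
  # the slow half covered bins 0..49 first; only fast samples remain
  expect_equal(sum(occ_fast$seconds > 0), 50)
  expect_equal(sum(occ_fast$p), 1, tolerance = 1e-12)
  expect_error(compute_occupancy(tr, geometry(50), min_speed = 100),
               "empty occupancy")
})

test_that("rates are spike counts over occupancy seconds", {
  # 2 bins, one trial of 3 s: 1.5 s in each bin, 3 spikes land in bin 0
  tr <- position_trace(times = seq(0.25, 2.75, by = 0.5),
                       positions = c(0.2, 0.4, 0.6, 1.2, 1.4, 1.6),
                       speed = rep(10, 6))
  win <- data.frame(trial = 1, t_start_s = 0, t_end_s = 3)
  spikes <- c(0.3, 0.7, 1.1)
  m <- spike_rate_matrix(spikes, tr, geometry(2), win)
  expect_equal(m$occupancy_seconds[1, ], c(1.5, 1.5), tolerance = 1e-9)
  expect_equal(unname(m$rates[1, ]), c(2, 0), tolerance = 1e-9)

  # no spikes: zero rates on occupied bins, not NA
  m0 <- spike_rate_matrix(numeric(0), tr, geometry(2), win)
  expect_equal(unname(m0$rates[1, ]), c(0, 0))
})

test_that("rate x occupancy reproduces spike counts exactly per trial", {
  p <- place_field_params(peak = 15, mu = 25, sigma = 4, baseline = 2,
                          noise_sd = 0)
  truth <- simulate_trials(p, geometry(50), 8, seed = 4)
  sp <- synthesize_spikes(truth, trial_duration_s = 25, seed = 8)
  tr <- position_trace(sp$trace$time_s, sp$trace$position, sp$trace$trial)
  m <- spike_rate_matrix(sp$spikes, tr, geometry(50), sp$trial_windows)
  expect_equal(m$dropped_spikes, 0)
  recovered <- rowSums(m$rates * m$occupancy_seconds, na.rm = TRUE)
  counted <- vapply(seq_len(8), function(t)
    sum(sp$spikes >= sp$trial_windows$t_start_s[t] &
        sp$spikes < sp$trial_windows$t_end_s[t]), numeric(1))
  expect_equal(recovered, counted, tolerance = 1e-9)

  # binning refinement: doubling bin count conserves the same identity
  m100 <- spike_rate_matrix(sp$spikes, tr, geometry(100), sp$trial_windows)
  rec100 <- rowSums(m100$rates * m100$occupancy_seconds, na.rm = TRUE)
  expect_equal(rec100, counted, tolerance = 1e-9)
})

test_that("constant-rate spikes are recovered at the right rate", {
  m_true <- matrix(10, 20, 50)
  sp <- synthesize_spikes(m_true, trial_duration_s = 50, seed = 15)
  tr <- position_trace(sp$trace$time_s, sp$trace$position, sp$trace$trial)
  m <- spike_rate_matrix(sp$spikes, tr, geometry(50), sp$trial_windows)
  # total spikes ~ Poisson(10 Hz * 1000 s); per-bin averages near 10 Hz
  expect_equal(mean(m$rates), 10, tolerance = 0.15)
  expect_true(all(abs(colMeans(m$rates) - 10) < 4 * sqrt(10 / 20)))
})

test_that("spikes outside windows are dropped and reported", {
  tr <- uniform_trace(duration = 50)
  win <- data.frame(trial = 1, t_start_s = 0, t_end_s = 50)
  expect_message(
    m <- spike_rate_matrix(c(1, 2, 60, 70), tr, geometry(50), win),
    "2 spike"
  )
  expect_equal(m$dropped_spikes, 2)
  expect_equal(sum(m$spike_counts), 2)
})

test_that("smoothing is conservative, identity at sd 0, flat-invariant", {
  m <- default_matrix(seed = 20)
  expect_identical(smooth_map(m, 0), m)

  flat <- matrix(3, 5, 40)
  expect_equal(smooth_map(flat, 2), flat, tolerance = 1e-12)

  # mass supported away from the edges is conserved exactly: the
  # renormalised kernel's column sums are 1 for interior source bins
  # (bins closer than two kernel radii to an edge feed into renormalised,
  # truncated kernels, so their mass is redistributed, not conserved)
  interior <- m
  interior$rates[, c(1:10, 41:50)] <- 0
  sm <- smooth_map(interior, 1.5)   # kernel radius 5: margin of 10 suffices
  expect_equal(rowMeans(sm$rates), rowMeans(interior$rates), tolerance = 1e-9)

  # 2D: flat invariance under the separable kernel
  g2 <- geometry(c(10, 10))
  flat2 <- trial_rate_matrix(matrix(2, 4, 100), g2)
  expect_equal(smooth_map(flat2, 1)$rates, flat2$rates, tolerance = 1e-12)

  # 2D: an interior point source keeps its total mean and flattens its peak
  point <- matrix(0, 2, 100)
  point[, 45] <- 10   # bin (4, 4), row-major with y fastest
  m2 <- trial_rate_matrix(point, g2)
  sm2 <- smooth_map(m2, 0.5)   # kernel radius 2: (4, 4) is interior enough
  expect_equal(rowMeans(sm2$rates), rowMeans(m2$rates), tolerance = 1e-9)
  expect_lt(max(sm2$rates), max(m2$rates))
})

test_that("rebinning requires a divisor and conserves rate mass", {
  m <- default_matrix(seed = 21)
  expect_error(rebin_matrix(m, 7L), "divisor")
  r10 <- rebin_matrix(m, 10L)
  expect_equal(r10$geometry$total_bins, 10)
  # uniform occupancy: total rate x occupancy conserved per trial
  expect_equal(rowMeans(r10$rates), rowMeans(m$rates), tolerance = 1e-12)
})

test_that("qc rules fire individually and pass clean summaries", {
  base <- list(mean_rate_hz = 1, n_spikes = 60, n_trials = 20,
               trial_durations_s = rep(10, 20) + seq(-0.5, 0.5, length.out = 20),
               presence_ratio = 0.8)
  ok <- qc_filter(base)
  expect_true(ok$keep)
  expect_length(ok$violations, 0)

  cases <- list(
    list(field = "mean_rate_hz", value = 0.1, rule = "min_rate"),
    list(field = "mean_rate_hz", value = 25, rule = "max_rate"),
    list(field = "n_spikes", value = 49, rule = "min_spikes"),
    list(field = "n_trials", value = 14, rule = "min_trials"),
    list(field = "presence_ratio", value = 0.4, rule = "min_presence")
  )
  for (cs in cases) {
    s <- base
    s[[cs$field]] <- cs$value
    res <- qc_filter(s)
    expect_false(res$keep)
    expect_true(cs$rule %in% res$violations)
  }

  s <- base
  s$trial_durations_s <- c(rep(10, 19), 30)   # one wild trial duration
  res <- qc_filter(s)
  expect_false(res$keep)
  expect_true("max_duration_sd" %in% res$violations)
  expect_equal(res$trials_excluded, 20L)
})

test_that("edge-bin masking blanks exactly the requested bins", {
  m <- default_matrix(seed = 22)
  mm <- mask_edge_bins(m, 3)
  expect_true(all(is.na(mm$rates[, c(1:3, 48:50)])))
  expect_false(anyNA(mm$rates[, 4:47]))
  # metrics still run on the masked matrix
  expect_true(is.finite(anova_f(mm)$f))
})
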