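test_that("tuning profile matches the closed-form Gaussian-plus-baseline", {
  g <- geometry(50)
  p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1,
                          noise_sd = 0)
  prof <- tuning_profile(p, g)
  expect_length(prof, 50)
  expect_equal(prof[26], 11.0, tolerance = 1e-12)                 # x = mu
  expect_equal(prof[29], 10 * exp(-1 / 2) + 1, tolerance = 1e-12) # x = mu + sigma

  flat <- tuning_profile(place_field_params(peak = 0, baseline = 2), g)
  expect_equal(flat, rep(2, 50))

  expect_error(tuning_profile(place_field_params(mu = 60), g),
               "center out of range")
  expect_error(tuning_profile(place_field_params(mu = c(5, 5)), g),
               "center out of range")

  # 2D: peak + baseline at the centre bin, isotropic fall-off
  g2 <- geometry(c(10, 10))
  p2 <- place_field_params(peak = 8, mu = c(4, 4), sigma = 2, baseline = 0.5)
  prof2 <- tuning_profile(p2, g2)
  co <- bin_coords(g2)
  centre <- which(co[, 1] == 4 & co[, 2] == 4)
  expect_equal(prof2[centre], 8.5, tolerance = 1e-12)
  one_off <- which(co[, 1] == 5 & co[, 2] == 4)
  expect_equal(prof2[one_off], 8 * exp(-1 / 8) + 0.5, tolerance = 1e-12)
})

test_that("degenerate noise gives identical trials equal to the profile", {
  g <- geometry(50)
  p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1,
                          noise_sd = 0, jitter_max = 0, presence = 1)
  m <- simulate_trials(p, g, 5, seed = 11)
  expect_equal(m$n_trials, 5)
  prof <- tuning_profile(p, g)
  for (t in 1:5) expect_equal(unname(m$rates[t, ]), prof, tolerance = 1e-12)
})

test_that("absent fields are baseline plus noise only", {
  g <- geometry(50)
  p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1,
                          noise_sd = 0.5, presence = 0)
  m <- simulate_trials(p, g, 200, seed = 3)
  trial_means <- rowMeans(m$rates)
  # spatial mean of baseline + noise: 1 Hz (tiny positive clipping bias)
  expect_true(all(abs(trial_means - 1) < 4 * 0.5 / sqrt(50) + 0.01))
  # no elevated field region anywhere
  expect_true(all(apply(m$rates, 1, max) < 1 + 5 * 0.5))
})

test_that("presence ratio controls per-trial field expression", {
  g <- geometry(50)
  p <- place_field_params(peak = 10, mu = 25, sigma = 3, baseline = 1,
                          noise_sd = 0.5, presence = 0.5)
  m <- simulate_trials(p, g, 2000, seed = 7)
  thr <- 1 + 3 * 0.5
  frac <- mean(apply(m$rates, 1, max) > thr)
  # oracle: present trials always exceed (peak 11); absent trials exceed when
  # the max of 50 iid N(1, 0.5) noise bins crosses the threshold
  p_absent <- 1 - stats::pnorm(3)^50
  expected <- 0.5 + 0.5 * p_absent
  ci <- binom99(expected, 2000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("simulation is deterministic in (params, seed)", {
  p <- place_field_params(noise_sd = 1, jitter_max = 2, presence = 0.8)
  g <- geometry(50)
  m1 <- simulate_trials(p, g, 20, seed = 123)
  m2 <- simulate_trials(p, g, 20, seed = 123)
  m3 <- simulate_trials(p, g, 20, seed = 124)
  expect_identical(m1$rates, m2$rates)
  expect_false(identical(m1$rates, m3$rates))
})

test_that("across-trial mean map converges to the tuning profile", {
  g <- geometry(50)
  p <- place_field_params(peak = 10, mu = 25, sigma = 5, baseline = 5,
                          noise_sd = 1, jitter_max = 0, presence = 1)
  n <- 10000
  m <- simulate_trials(p, g, n, seed = 99)
  dev <- abs(colMeans(m$rates) - tuning_profile(p, g))
  expect_lt(max(dev), 4 * 1 / sqrt(n))
})

test_that("clipping only ever raises values", {
  p <- place_field_params(peak = 2, baseline = 0.5, noise_sd = 2)
  g <- geometry(50)
  raw <- simulate_trials(p, g, 50, seed = 5, clip = FALSE)
  clp <- simulate_trials(p, g, 50, seed = 5, clip = TRUE)
  expect_true(any(raw$rates < 0))          # clipping actually exercised
  diff_mask <- raw$rates != clp$rates
  expect_true(all(raw$rates[diff_mask] < 0))
  expect_true(all(clp$rates[diff_mask] == 0))
  expect_true(all(clp$rates >= 0))
})

test_that("jitter offsets respect the requested mode", {
  g <- geometry(50)
  p <- place_field_params(noise_sd = 0, jitter_max = 5, presence = 1)
  m_pos <- simulate_trials(p, g, 500, seed = 2, jitter_mode = "positive")
  off_pos <- m_pos$provenance$offsets
  expect_true(all(off_pos >= 0 & off_pos <= 5))
  m_sym <- simulate_trials(p, g, 500, seed = 2, jitter_mode = "symmetric")
  off_sym <- m_sym$provenance$offsets
  expect_true(all(off_sym >= -5 & off_sym <= 5))
  expect_true(any(off_sym < 0))
})

test_that("evenly spaced sweeps hit both endpoints with constant step", {
  spec <- sweep_spec("width", 1, 20, 1000, "evenly_spaced",
                     fixed = place_field_params(noise_sd = 0), n_trials = 2,
                     seed = 1)
  pop <- sample_population(spec)
  sig <- vapply(pop$params, function(p) p$sigma, numeric(1))
  expect_equal(min(sig), 1)
  expect_equal(max(sig), 20)
  expect_equal(diff(sig), rep(diff(sig)[1], 999), tolerance = 1e-12)

  two <- sample_population(sweep_spec("width", 1, 20, 2, "evenly_spaced",
                                      n_trials = 2, seed = 1))
  expect_equal(two$values, c(1, 20))
  one <- sample_population(sweep_spec("width", 1, 20, 1, "evenly_spaced",
                                      n_trials = 2, seed = 1))
  expect_equal(one$values, 1)
})

test_that("uniform random sweeps stay in range with the right mean", {
  spec <- sweep_spec("peak", 1, 20, 1000, "uniform_random",
                     fixed = place_field_params(noise_sd = 0), n_trials = 2,
                     seed = 42)
  pop <- sample_population(spec)
  a <- pop$values
  expect_true(all(a >= 1 & a <= 20))
  se <- (20 - 1) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(a) - 10.5), 3 * se)
})

test_that("any population neuron is reproducible in isolation", {
  spec <- sweep_spec("noise", 0.5, 3, 10, fixed = place_field_params(),
                     n_trials = 10, seed = 77)
  pop <- sample_population(spec)
  i <- 7
  redo <- simulate_trials(pop$params[[i]], pop$geometry, 10,
                          seed = pop$seeds[i])
  expect_identical(pop$matrices[[i]]$rates, redo$rates)
})

test_that("Poisson spike synthesis matches its rate budget and contract", {
  zero <- synthesize_spikes(matrix(0, 4, 10), 10, seed = 1)
  expect_length(zero$spikes, 0)

  m <- matrix(10, 10, 50)  # constant 10 Hz, 10 trials x 10 s = 100 s
  out <- synthesize_spikes(m, 10, seed = 21)
  n <- length(out$spikes)
  expect_gt(n, stats::qpois(0.005, 1000))
  expect_lt(n, stats::qpois(0.995, 1000))
  expect_false(is.unsorted(out$spikes, strictly = TRUE))
  expect_true(all(out$spikes >= 0 & out$spikes <= 100))
  # position trace covers every bin on every trial
  for (tr in c(1, 5, 10)) {
    seg <- out$trace[out$trace$trial == tr, ]
    expect_setequal(unique(floor(seg$position)), 0:49)
  }
})

test_that("SI and F treat 2D bins as unordered categories", {
  # a 2D matrix and the same values read as a 100-bin 1D matrix agree
  g2 <- geometry(c(10, 10))
  p2 <- place_field_params(peak = 10, mu = c(4, 4), sigma = 1.5,
                           baseline = 1, noise_sd = 1)
  m2 <- simulate_trials(p2, g2, 20, seed = 31)
  m1 <- trial_rate_matrix(m2$rates, geometry(100))
  expect_equal(spatial_information(tuning_curve(m2)),
               spatial_information(tuning_curve(m1)), tolerance = 1e-12)
  expect_equal(anova_f(m2)$f, anova_f(m1)$f, tolerance = 1e-12)
})
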