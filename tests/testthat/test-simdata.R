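test_that("power-law noise has the requested spectral slope and unit variance", {
  # white-noise limit
  x0 <- gen_powerlaw_noise(4096, 500, 0, seed = 1)
  expect_lt(abs(welch_slope(x0, 500)), 0.15)
  # pink-ish noise, slope averaged over seeds
  sl <- mean(vapply(1:20, function(s) {
    welch_slope(gen_powerlaw_noise(8192, 500, 1, seed = s), 500)
  }, 0))
  expect_lt(abs(sl - (-1)), 0.15)
  # unit sample variance by construction, any beta
  for (b in c(0, 0.7, 1.5, 2.5)) {
    expect_equal(var(gen_powerlaw_noise(1024, 250, b, seed = 3)), 1,
                 tolerance = 1e-9)
  }
  expect_error(gen_powerlaw_noise(1, 500, 1), class = "invalid_argument")
  expect_error(gen_powerlaw_noise(100, -1, 1), class = "invalid_argument")
})

test_that("spectral slope recovery holds across the study's beta range", {
  for (b in c(0.5, 1.0, 1.5)) {
    sl <- mean(vapply(1:10, function(s) {
      welch_slope(gen_powerlaw_noise(8192, 500, b, seed = s), 500)
    }, 0))
    expect_lt(abs(sl - (-b)), 0.2)
  }
})

test_that("amplitude-modulated oscillation peaks at its carrier with a slow envelope", {
  fs <- 500; n <- 8192
  o <- gen_am_oscillation(n, fs, osc_freq = 10, seed = 2)
  sp <- stats::spec.pgram(stats::ts(o$signal, frequency = fs), spans = 5,
                          plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 10), 0.5)
  # envelope spectral content below the low-pass cutoff
  env <- o$envelope - mean(o$envelope)
  spe <- stats::spec.pgram(stats::ts(env, frequency = fs), plot = FALSE)
  frac_below <- sum(spe$spec[spe$freq <= 1]) / sum(spe$spec)
  expect_gt(frac_below, 0.95)
  expect_true(all(o$envelope >= 0.05))
  # degenerate envelope: zero modulation depth
  o0 <- gen_am_oscillation(512, 500, mod_depth = 0, seed = 1)
  expect_lt(stats::sd(o0$envelope), 1e-9)
  expect_error(gen_am_oscillation(512, 500, osc_freq = 10, am_cutoff = 12),
               class = "invalid_argument")
})

test_that("evoked responses follow their coupling contracts", {
  fs <- 500
  time <- (0:1999) / fs - 2
  trial <- list(noise = rep(0, 2000), envelope = rep(1, 2000),
                carrier = sin(2 * pi * 10 * (time + 2)), time = time)
  cfg <- sim_config(response_kind = "none")
  out <- apply_evoked_response(trial, prestim_value = 0.7, cfg)
  expect_identical(out$signal, trial$noise + trial$carrier)
  expect_identical(out$amplitude, 0)

  # additive coupled: peak deflection = gain * prestim value
  cfg <- sim_config(response_kind = "additive_coupled", response_gain = 2,
                    response_duration = 0.6)
  out <- apply_evoked_response(trial, prestim_value = 0.7, cfg)
  expect_equal(max(out$evoked), 2 * 0.7, tolerance = 1e-4)
  expect_equal(out$amplitude, 1.4)

  # desync with full depth: envelope reaches 0 at the lobe midpoint
  cfg <- sim_config(response_kind = "desync", desync_depth = 1,
                    response_duration = 0.6)
  out <- apply_evoked_response(trial, prestim_value = 0, cfg)
  mid <- which.min(abs(time - 0.3))
  expect_lt(out$envelope[mid], 1e-6)
  # desync without a separable oscillation is an invalid state
  expect_error(
    apply_evoked_response(list(noise = rnorm(10), envelope = NULL,
                               carrier = NULL, time = (0:9) / fs),
                          0, cfg),
    class = "invalid_state")
})

test_that("gen_dataset is deterministic with the documented shape and SNR", {
  cfg <- sim_config(n_subjects = 2, n_trials = 4, trial_duration = 4,
                    sampling_rate = 500, seed = 7)
  ds1 <- gen_dataset(cfg)
  ds2 <- gen_dataset(cfg)
  expect_identical(ds1$epochs[[1]]$data, ds2$epochs[[1]]$data)
  expect_identical(ds1$ground_truth, ds2$ground_truth)
  expect_equal(dim(ds1$epochs[[1]]$data), c(4L, 1L, 2000L))
  expect_equal(range(ds1$epochs[[1]]$time), c(-2, 2 - 1 / 500))
  expect_equal(nrow(ds1$ground_truth), 8L)
  # degenerate SNR distribution: every realized SNR equals the base
  expect_true(all(ds1$ground_truth$snr == cfg$snr_base))
})

test_that("coupling ground truth matches the response kind", {
  cfg <- sim_config(n_subjects = 1, n_trials = 128, response_gain = 1,
                    response_kind = "additive_coupled", seed = 5)
  gt <- gen_dataset(cfg)$ground_truth
  expect_equal(cor(gt$prestim_value, gt$amplitude), 1, tolerance = 1e-12)
  cfg$response_kind <- "additive_uncoupled"
  gt <- gen_dataset(cfg)$ground_truth
  expect_lt(abs(cor(gt$prestim_value, gt$amplitude)), 0.2)
})

test_that("the SNR grid pairs coupled and uncoupled controls per cell", {
  lv <- c(1 / 64, 1 / 16, 1 / 4, 1, 4, 16, 64)
  base <- sim_config(n_subjects = 2, n_trials = 4)
  grid <- gen_snr_grid(lv, base = base)
  expect_equal(nrow(grid), 49L * 2L)
  expect_equal(sum(grid$kind == "additive_coupled"), 49L)
  g1 <- gen_snr_grid(1, base = base)
  expect_equal(nrow(g1), 2L)
  # paired configs differ only in response_kind
  a <- g1$config[[1]]; b <- g1$config[[2]]
  a$response_kind <- NULL; b$response_kind <- NULL
  expect_identical(unclass(a), unclass(b))
  expect_error(gen_snr_grid(numeric(0)), class = "invalid_argument")
  expect_error(gen_snr_grid(c(1, -2)), class = "invalid_argument")
})
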