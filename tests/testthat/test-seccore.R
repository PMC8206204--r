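test_that("median split follows the sorting, tie and odd-count rules", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s), c("low", "low", "high", "high"))
  # ties broken by trial order: last two indices go high
  s <- median_split(c(5, 5, 5, 5))
  expect_equal(as.character(s), c("low", "low", "high", "high"))
  # odd count: middle trial goes low
  s <- median_split(c(1, 2, 3))
  expect_equal(as.character(s), c("low", "low", "high"))
  expect_equal(sum(s == "high"), 1L)
  expect_error(median_split(c(1, NA)), class = "invalid_argument")
  expect_error(median_split(3), class = "invalid_argument")
  # group sizes never differ by more than one
  for (n in 5:9) {
    s <- median_split(rnorm(n))
    expect_lte(abs(sum(s == "high") - sum(s == "low")), 1L)
  }
})

test_that("percent change normalizes power-like signals and rejects others", {
  expect_equal(percent_change(12, 10), 20)
  x <- array(5, c(2, 3, 4))
  expect_true(all(percent_change(x, c(5, 5, 5)) == 0))
  expect_error(percent_change(12, 0), class = "invalid_argument")
  expect_error(percent_change(12, -3), class = "invalid_argument")
})

test_that("pseudotrial correction subtracts groupwise and differences high-low", {
  rh <- matrix(2, 1, 5); rl <- matrix(1, 1, 5)
  ph <- matrix(0.5, 1, 5); pl <- matrix(0.25, 1, 5)
  cc <- pseudotrial_correct(rh, rl, ph, pl)
  expect_true(all(cc$corrected_high == 1.5))
  expect_true(all(cc$corrected_low == 0.75))
  expect_true(all(cc$difference == 0.75))
  # zero pseudotrials: degenerate passthrough
  cc <- pseudotrial_correct(rh, rl, ph * 0, pl * 0)
  expect_identical(cc$corrected_high, rh)
  expect_error(pseudotrial_correct(rh, rl, ph, matrix(0, 2, 5)),
               class = "invalid_argument")
})

test_that("TTV time course follows the law-of-total-variance arithmetic", {
  time <- (0:99) / 100 - 0.5
  # two trials constant at 1 and 3: SD = sqrt(2) always -> 0% change
  x <- array(NA_real_, c(2, 1, 100))
  x[1, 1, ] <- 1; x[2, 1, ] <- 3
  tc <- ttv(x, time, c(-0.1, 0))
  expect_lt(max(abs(tc)), 1e-9)
  expect_equal(unname(attr(tc, "sd")[1, 1]), sqrt(2))
  # identical trials: zero SD baseline is degenerate
  x2 <- array(1, c(3, 1, 100))
  expect_error(ttv(x2, time, c(-0.1, 0)), class = "degenerate_baseline")
  # per-trial offset cancelled post-stimulus: percent change -> -100
  set.seed(1)
  offs <- rnorm(6)
  x3 <- array(NA_real_, c(6, 1, 100))
  for (i in 1:6) x3[i, 1, ] <- offs[i] * c(rep(1, 50), rep(0, 50))
  tc3 <- ttv(x3, time, c(-0.1, 0))
  expect_equal(unname(tc3[1, 100]), -100)
})

test_that("the variance-of-sum identity holds exactly on samples", {
  set.seed(42)
  for (i in 1:20) {
    X <- rnorm(30); Y <- 0.5 * X + rnorm(30)
    v <- total_variance_oracle(X, Y)
    lhs <- v$sigma_total^2
    rhs <- v$sigma_X^2 + v$sigma_Y^2 + 2 * v$r_XY * v$sigma_X * v$sigma_Y
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  X <- rnorm(10)
  v <- total_variance_oracle(X, -X)
  expect_equal(v$sigma_total, 0, tolerance = 1e-12)
  expect_equal(v$r_XY, -1, tolerance = 1e-12)
  v2 <- total_variance_oracle(X, X)
  expect_equal(v2$sigma_total, 2 * v2$sigma_X, tolerance = 1e-12)
  # independent components: correlation term vanishes at large n
  set.seed(7)
  A <- rnorm(10000); B <- rnorm(10000)
  v3 <- total_variance_oracle(A, B)
  expect_lt(abs(v3$r_XY), 0.05)
  expect_equal(v3$sigma_total^2, v3$sigma_X^2 + v3$sigma_Y^2,
               tolerance = 0.05)
  expect_error(total_variance_oracle(rep(1, 5), rnorm(5)),
               class = "invalid_argument")
})

test_that("summary index integrates signed in-mask values", {
  tc <- matrix(2, 1, 10)
  mask <- matrix(FALSE, 1, 10); mask[1, 1:5] <- TRUE
  expect_equal(unname(summary_index(tc, mask, 0.002)), 0.02)
  expect_true(is.na(summary_index(tc, mask & FALSE, 0.002)))
  tc2 <- matrix(c(rep(1, 5), rep(-1, 5)), 1, 10)
  expect_equal(unname(summary_index(tc2, !mask | mask, 0.002)), 0)
})

test_that("pseudotrial difference is null without a stimulus and positive with coupling", {
  # no-stimulus null: corrected difference within sampling error of zero
  cfg <- sim_config(n_subjects = 12, n_trials = 64, trial_duration = 4,
                    sampling_rate = 250, response_kind = "none", seed = 31)
  ds <- gen_dataset(cfg)
  diffs <- t(vapply(ds$epochs, function(ep) {
    est <- sec_estimate(ep, windows = window_spec())
    as.vector(est$corrected$difference)
  }, numeric(200)))
  m <- colMeans(diffs)
  sem <- apply(diffs, 2, sd) / sqrt(nrow(diffs))
  expect_lt(mean(abs(m) > 3 * sem), 0.05)
  # coupled responses with positive gain: time-averaged difference > 0
  cfg2 <- sim_config(n_subjects = 12, n_trials = 64, trial_duration = 4,
                     sampling_rate = 250, response_kind = "additive_coupled",
                     response_gain = 1, seed = 32)
  ds2 <- gen_dataset(cfg2)
  diffs2 <- vapply(ds2$epochs, function(ep) {
    mean(sec_estimate(ep, windows = window_spec())$corrected$difference)
  }, 0)
  expect_gt(mean(diffs2), 0)
  expect_gt(mean(diffs2 > 0), 0.8)
})
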