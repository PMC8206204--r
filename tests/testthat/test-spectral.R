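test_that("wavelet power scales quadratically and is flat for stationary input", {
  fs <- 500; n <- 2000
  time <- (0:(n - 1)) / fs - 2
  # build trials x channels x samples explicitly
  e1 <- epochs_set(array(0, c(2, 1, n)), time = time, sampling_rate = fs)
  e1$data[1, 1, ] <- sin(2 * pi * 10 * (time + 2))
  e1$data[2, 1, ] <- 2 * sin(2 * pi * 10 * (time + 2))
  tfr <- morlet_tfr(e1, freqs = c(5, 10, 20), n_cycles = 3)
  mid <- 500:1500
  p1 <- mean(tfr$power[1, 1, 2, mid]); p2 <- mean(tfr$power[2, 1, 2, mid])
  expect_equal(p2 / p1, 4, tolerance = 0.01)
  # power at the carrier is constant over central samples
  expect_lt(sd(tfr$power[1, 1, 2, mid]) / p1, 0.01)
  # off-carrier power negligible; zero signal gives zero power
  expect_lt(mean(tfr$power[1, 1, 1, mid]) / p1, 0.01)
  e0 <- epochs_set(array(0, c(2, 1, n)), time = time, sampling_rate = fs)
  tfr0 <- morlet_tfr(e0, freqs = c(10), n_cycles = 3)
  expect_true(all(tfr0$power[, , , mid] == 0))
  # edge samples are flagged invalid
  expect_true(all(is.na(tfr$power[1, 1, 1, 1:10])))
  expect_error(morlet_tfr(e1, freqs = c(10, 300)), class = "invalid_argument")
})

test_that("alpha peak detection finds bumps and ignores pure 1/f spectra", {
  f <- seq(2, 30, by = 0.25)
  bg <- 10 * f^-1.2
  bump <- 6 * exp(-(f - 10.5)^2 / (2 * 1.5^2)) * 10 * 10.5^-1.2
  det <- detect_alpha_band(bg + bump, f)
  expect_false(is.null(det))
  expect_lt(abs(det$peak - 10.5), 0.5)
  expect_true(det$band[1] < det$peak && det$band[2] > det$peak)
  expect_null(detect_alpha_band(bg, f))
  expect_error(detect_alpha_band(c(-1, bg[-1]), f), class = "invalid_argument")

  # band scheme: individualized edges tile [2, 30] with no gaps
  sch <- band_scheme(det)
  expect_equal(sch$delta, c(2, 4))
  expect_equal(sch$theta[2], sch$alpha[1])
  expect_equal(sch$alpha[2], sch$beta[1])
  expect_equal(sch$beta[2], 30)
  # fallback scheme without a peak
  sch0 <- band_scheme(NULL)
  expect_equal(sch0$theta, c(4, 8))
  expect_equal(sch0$alpha, c(8, 13))
  expect_equal(sch0$beta, c(13, 30))
})

test_that("band power averages exactly the in-band frequencies", {
  fs <- 500; n <- 1000
  time <- (0:(n - 1)) / fs - 1
  e <- make_noise_epochs(n_trials = 2, fs = fs, span = c(-1, 1), seed = 3)
  freqs <- log_freqs(50, 2, 200)
  tfr <- morlet_tfr(e, freqs = freqs, n_cycles = 3)
  # the 50 log-spaced frequencies in [2, 4] are exactly the first 8
  in_band <- which(freqs >= 2 & freqs <= 4)
  expect_identical(in_band, 1:8)
  bp <- band_power(tfr, c(2, 4))
  manual <- apply(tfr$power[, , in_band, , drop = FALSE], c(1, 2, 4),
                  mean, na.rm = TRUE)
  expect_equal(bp, manual, tolerance = 1e-12)
  # single in-band frequency reduces to that frequency's power
  bp1 <- band_power(tfr, c(freqs[10] - 1e-6, freqs[10] + 1e-6))
  expect_equal(bp1[1, 1, 500], tfr$power[1, 1, 10, 500])
  expect_error(band_power(tfr, c(300, 400)), class = "invalid_argument")
})

test_that("fractal fits recover exact power laws in either spacing", {
  f_lin <- seq(2, 85, by = 0.5)
  ft <- fit_fractal(10 * f_lin^-1.5, f_lin, c(2, 85))
  expect_equal(ft$beta, 1.5, tolerance = 1e-9)
  expect_equal(ft$offset, 10, tolerance = 1e-9)
  ft2 <- fit_fractal(rep(3.5, length(f_lin)), f_lin, c(2, 85))
  expect_equal(ft2$beta, 0, tolerance = 1e-12)
  expect_equal(ft2$offset, 3.5, tolerance = 1e-9)
  # log-spaced grid gives the identical exponent for an exact power law
  f_log <- exp(seq(log(2), log(85), length.out = 80))
  ft3 <- fit_fractal(10 * f_log^-1.5, f_log, c(2, 85))
  expect_equal(ft3$beta, ft$beta, tolerance = 1e-9)
  expect_error(fit_fractal(c(-1, f_lin[-1]), f_lin), class = "invalid_argument")
})

test_that("IRASA separates fractal slopes and oscillatory peaks", {
  fs <- 500; cfg <- irasa_config()
  expect_false(2 %in% cfg$hset)
  # slope recovery across the study's range (10 seeds each)
  for (b in c(0.5, 1.0, 1.5)) {
    betas <- vapply(1:10, function(s) {
      x <- gen_powerlaw_noise(8000, fs, b, seed = s)[2001:4000]
      r <- irasa(x, fs, cfg)
      fit_fractal(r$fractal, r$freqs, c(2, 85))$beta
    }, 0)
    expect_lt(abs(mean(betas) - b), 0.2)
  }
  # mixed = fractal + oscillatory exactly, by construction
  x <- gen_powerlaw_noise(4000, fs, 1, seed = 1)[1001:2750]
  r <- irasa(x, fs, cfg)
  expect_equal(r$mixed, r$fractal + r$oscillatory, tolerance = 1e-12)
  expect_error(irasa(rnorm(100), fs, cfg), class = "window_error")
})

test_that("a sinusoid in white noise shows an in-band oscillatory peak over a flat fractal", {
  fs <- 500; cfg <- irasa_config()
  stats_10 <- vapply(1:10, function(s) {
    set.seed(s)
    x <- sin(2 * pi * 10 * (0:749) / fs + runif(1, 0, 2 * pi)) +
      0.5 * rnorm(750)
    r <- irasa(x, fs, cfg)
    c(fit_fractal(r$fractal, r$freqs, c(2, 85))$beta,
      r$freqs[which.max(r$oscillatory)])
  }, numeric(2))
  expect_lt(abs(mean(stats_10[1, ])), 0.2)
  expect_true(all(stats_10[2, ] >= 8 & stats_10[2, ] <= 13))
})

test_that("band-mean oscillatory power vanishes for scale-free input", {
  fs <- 500; cfg <- irasa_config()
  bands <- list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, 85))
  osum <- fsum <- numeric(5)
  for (s in 1:40) {
    x <- gen_powerlaw_noise(8000, fs, 1.5, seed = 500 + s)[2001:4000]
    r <- irasa(x, fs, cfg)
    for (b in 1:5) {
      sel <- r$freqs >= bands[[b]][1] & r$freqs <= bands[[b]][2]
      osum[b] <- osum[b] + mean(r$oscillatory[sel])
      fsum[b] <- fsum[b] + mean(r$fractal[sel])
    }
  }
  expect_true(all(abs(osum / fsum) < 0.10))
})

test_that("sliding IRASA is time-stable on stationary input with the stated grid", {
  # output grid: 0.9 s span at 20 ms steps = 46 points
  expect_length(seq(-0.1, 0.8, by = 0.02), 46L)
  fs <- 250
  set.seed(8)
  n <- 5 * fs
  dat <- array(NA_real_, c(2, 1, n))
  for (i in 1:2) dat[i, 1, ] <- gen_powerlaw_noise(n, fs, 1, seed = 20 + i)
  ep <- epochs_set(dat, time = (0:(n - 1)) / fs - 2.5, sampling_rate = fs)
  sl <- irasa_sliding(ep, irasa_config(freq_range = c(2, 60)),
                      out_times = seq(-0.1, 0.1, by = 0.02),
                      bands = list(alpha = c(8, 13)))
  # stationary input: fitted beta varies little across windows
  for (i in 1:2) {
    expect_lt(max(sl$beta[i, 1, ]) - min(sl$beta[i, 1, ]), 0.35)
  }
  expect_true(all(is.finite(sl$offset)))
  # negative oscillatory band means are propagated as missing, not negative
  expect_true(all(is.na(sl$osc_band) | sl$osc_band >= 0))
})
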