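test_that("window arithmetic holds for all prestimulus-length variants", {
  for (L in c(0.05, 0.1, 0.2)) {
    ws <- window_spec(prestim_length = L)
    expect_equal(ws$prestim, c(-L, 0))
    expect_equal(diff(ws$prestim), diff(ws$pseudo_prestim))
    # pseudo response duration always equals the real response duration
    expect_equal(diff(ws$pseudo_trial), diff(ws$poststim))
    # pseudo windows precede and never overlap the real prestim window
    expect_lte(ws$pseudo_trial[2], ws$prestim[1])
    expect_lte(ws$pseudo_prestim[2], ws$pseudo_trial[1])
  }
  ws <- window_spec()
  expect_equal(ws$pseudo_trial, c(-0.9, -0.1))
  expect_equal(ws$pseudo_prestim, c(-1.0, -0.9))
  expect_error(window_spec(prestim_length = 0.3), class = "invalid_argument")
})

test_that("define_trials builds one matched pseudotrial per epoch", {
  ep <- make_noise_epochs(n_trials = 128, fs = 250, span = c(-1, 1))
  tab <- define_trials(ep, window_spec())
  expect_equal(nrow(tab), 256L)
  expect_equal(sum(tab$kind == "real"), 128L)
  expect_equal(sum(tab$kind == "pseudo"), 128L)
  ps <- tab[tab$kind == "pseudo", ]
  expect_true(all(abs(ps$resp_start - -0.9) < 1e-9 &
                    abs(ps$resp_end - -0.1) < 1e-9))
  # random placement is deterministic under a seed and stays eligible
  ep2 <- make_noise_epochs(n_trials = 16, fs = 250, span = c(-2, 1))
  ws <- window_spec(random_pseudo_placement = TRUE)
  t1 <- define_trials(ep2, ws, seed = 4)
  t2 <- define_trials(ep2, ws, seed = 4)
  expect_identical(t1, t2)
  p1 <- t1[t1$kind == "pseudo", ]
  expect_true(all(p1$resp_end <= -0.1 + 1e-9))
  expect_true(all(p1$prestim_start >= -2 - 1e-9))
  expect_gt(length(unique(p1$resp_start)), 1)
  # epochs too short for the requested windows
  expect_error(define_trials(ep, window_spec(prestim_length = 0.2)),
               class = "window_error")
})

test_that("prestimulus amplitude is the in-window arithmetic mean", {
  n <- 500
  time <- (0:(n - 1)) / 250 - 1
  dat <- array(3, c(2, 1, n))
  expect_true(all(prestim_amplitude(dat, c(-0.1, 0), time) == 3))
  # window covering samples {1, 2, 3} -> 2
  dat2 <- array(rep(seq_len(n), each = 2), c(2, 1, n))
  w <- c(time[1], time[4])
  expect_true(all(prestim_amplitude(dat2, w, time) == 2))
  # full cycle of a sinusoid averages to zero
  dat3 <- array(rep(sin(2 * pi * 10 * (time + 1)), each = 2), c(2, 1, n))
  expect_lt(max(abs(prestim_amplitude(dat3, c(-0.1, 0), time))), 1e-9)
  expect_error(prestim_amplitude(dat, c(5, 6), time), class = "window_error")
})

test_that("epochs round-trip losslessly through the feather layout", {
  ep <- make_noise_epochs(n_trials = 3, n_chan = 2, fs = 250,
                          span = c(-1, 1), seed = 9)
  ep$channel_positions <- cbind(c(0, 1), c(0, 0))
  f <- tempfile(fileext = ".feather")
  write_epochs(ep, f, "feather")
  back <- read_epochs(f, "feather")
  expect_identical(back$data, ep$data)
  expect_identical(back$time, ep$time)
  expect_identical(back$sampling_rate, ep$sampling_rate)
  expect_identical(back$channel_names, ep$channel_names)
  expect_equal(back$channel_positions, ep$channel_positions,
               ignore_attr = TRUE)
  # a feather table without the layout metadata is rejected
  f2 <- tempfile(fileext = ".feather")
  arrow::write_feather(data.frame(x = 1:3), f2)
  expect_error(read_epochs(f2, "feather"), class = "format_error")
  expect_error(read_epochs(tempfile(), "feather"), class = "format_error")
})

test_that("EDF round-trips to 16-bit precision and flags missing annotations", {
  ep <- make_noise_epochs(n_trials = 3, n_chan = 2, fs = 250,
                          span = c(-1, 1), seed = 2)
  f <- tempfile(fileext = ".edf")
  write_epochs(ep, f, "edf")
  back <- read_epochs(f, "edf", epoch_window = c(-1, 1))
  expect_equal(dim(back$data), dim(ep$data))
  rng <- max(ep$data) - min(ep$data)
  expect_lt(max(abs(back$data - ep$data)), rng / 65535 * 2)
  # an EDF file with no annotations channel is a format error
  raw <- readBin(f, "raw", file.info(f)$size)
  # forge the annotations label so no onset channel is found
  lab_off <- 256 + 2 * 16
  raw[(lab_off + 1):(lab_off + 16)] <- charToRaw(sprintf("%-16s", "notann"))
  f3 <- tempfile(fileext = ".edf")
  writeBin(raw, f3)
  expect_error(read_epochs(f3, "edf"), class = "format_error")
})
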