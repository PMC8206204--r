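# Generative simulations: 1/f^beta colored noise, an alpha oscillation whose
# amplitude is itself a slow 1/f process, and stimulus-evoked responses that
# are either additive (optionally coupled to pre-stimulus amplitude) or
# implemented as oscillatory desynchronization. These are the study
# conditions under which both spontaneous-evoked correlation estimators are
# validated.

#' Simulation configuration
#'
#' Bundles all parameters of the trial generator with validation. Defaults
#' reproduce the reference simulation cohort: 48 subjects, 128 four-second
#' trials sampled at 500 Hz, per-trial power-law exponents drawn uniformly
#' from \[0.5, 1.5\], a 10 Hz oscillation whose amplitude is a 1/f process
#' low-pass filtered at 1 Hz, and a 600 ms half-sine evoked response starting
#' at stimulus onset.
#'
#' @param n_subjects number of simulated subjects (>= 1).
#' @param n_trials trials per subject (>= 2).
#' @param trial_duration trial length in seconds; the time axis is centered
#'   on stimulus onset (a 4 s trial spans -2 s to +2 s).
#' @param sampling_rate sampling rate in Hz (> 2 * `osc_freq`).
#' @param beta_range interval of power-law exponents for the background
#'   noise; one exponent is drawn uniformly per trial. Must lie in \[0, 3\].
#' @param osc_freq oscillation frequency, Hz.
#' @param osc_mod_depth modulation depth of the oscillation envelope
#'   (envelope = 1 + depth * standardized slow 1/f process, floored at 0.05).
#' @param am_beta power-law exponent of the amplitude-modulation process.
#' @param am_cutoff low-pass cutoff of the amplitude process, Hz
#'   (< `osc_freq`).
#' @param response_kind one of `"additive_coupled"` (half-sine added with
#'   amplitude `response_gain * prestimulus value`), `"additive_uncoupled"`
#'   (amplitude `response_gain * u`, `u` a standard normal draw independent
#'   of the pre-stimulus), `"desync"` (oscillation envelope multiplied by
#'   `1 - desync_depth * lobe`), or `"none"`.
#' @param response_onset response start, seconds after stimulus onset.
#' @param response_duration half-sine lobe duration, seconds.
#' @param response_gain amplitude scale of additive responses. Sign matters:
#'   a negative gain with `"additive_coupled"` yields a negative
#'   spontaneous-evoked correlation (post-stimulus variability quenching).
#' @param desync_depth peak fractional envelope reduction for `"desync"`
#'   (1 = full suppression at the lobe midpoint).
#' @param snr_base base oscillation-to-noise power ratio.
#' @param snr_trial_sd SD of the per-trial log-normal SNR modulation:
#'   `snr = snr_base * exp(N(0, snr_trial_sd))`.
#' @param prestim_window window (seconds, half-open) over which the raw
#'   pre-stimulus value driving the coupling is averaged.
#' @param seed master seed; every random draw is derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 48L,
                       n_trials = 128L,
                       trial_duration = 4,
                       sampling_rate = 500,
                       beta_range = c(0.5, 1.5),
                       osc_freq = 10,
                       osc_mod_depth = 0.5,
                       am_beta = 1,
                       am_cutoff = 1,
                       response_kind = c("additive_coupled",
                                         "additive_uncoupled",
                                         "desync", "none"),
                       response_onset = 0,
                       response_duration = 0.6,
                       response_gain = 2,
                       desync_depth = 0.8,
                       snr_base = 1,
                       snr_trial_sd = 0,
                       prestim_window = c(-0.1, 0),
                       seed = 1L) {
  response_kind <- match.arg(response_kind)
  stopifnot(
    n_subjects >= 1, n_trials >= 2,
    trial_duration > 0, sampling_rate > 0,
    length(beta_range) == 2L, beta_range[1] <= beta_range[2],
    osc_freq > 0, osc_mod_depth >= 0,
    am_beta >= 0, response_duration > 0,
    desync_depth >= 0, desync_depth <= 1,
    snr_base > 0, snr_trial_sd >= 0
  )
  if (sampling_rate <= 2 * osc_freq) {
    stop_classed("invalid_argument",
                 "sampling_rate must exceed 2 * osc_freq (Nyquist)")
  }
  if (beta_range[1] < 0 || beta_range[2] > 3) {
    stop_classed("invalid_argument", "beta_range must lie within [0, 3]")
  }
  if (am_cutoff >= osc_freq) {
    stop_classed("invalid_argument", "am_cutoff must be below osc_freq")
  }
  half <- trial_duration / 2
  if (response_onset < -half || response_onset + response_duration > half) {
    stop_classed("invalid_argument",
                 "response window [%g, %g] s does not fit inside the trial",
                 response_onset, response_onset + response_duration)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    trial_duration = trial_duration, sampling_rate = sampling_rate,
    beta_range = beta_range, osc_freq = osc_freq,
    osc_mod_depth = osc_mod_depth, am_beta = am_beta, am_cutoff = am_cutoff,
    response_kind = response_kind, response_onset = response_onset,
    response_duration = response_duration, response_gain = response_gain,
    desync_depth = desync_depth, snr_base = snr_base,
    snr_trial_sd = snr_trial_sd, prestim_window = prestim_window,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate 1/f^beta colored noise
#'
#' Spectral-domain synthesis: the discrete spectrum of white Gaussian noise
#' is shaped by f^(-beta/2) (DC bin zeroed) and inverse-transformed, giving a
#' series whose expected power spectrum follows f^-beta exactly over the
#' resolvable range. The output is standardized to zero mean and unit sample
#' variance.
#'
#' @param n_samples series length (>= 2).
#' @param sampling_rate sampling rate, Hz.
#' @param beta power-law exponent (>= 0); `beta = 0` is white noise.
#' @param seed optional seed.
#' @return numeric vector of length `n_samples`.
#' @export
gen_powerlaw_noise <- function(n_samples, sampling_rate, beta, seed = NULL) {
  if (n_samples < 2 || sampling_rate <= 0) {
    stop_classed("invalid_argument",
                 "n_samples must be >= 2 and sampling_rate positive")
  }
  if (beta < 0) stop_classed("invalid_argument", "beta must be >= 0")
  n <- as.integer(n_samples)
  with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    k <- seq_len(n) - 1L
    f <- pmin(k, n - k) * sampling_rate / n   # two-sided frequency magnitude
    scale <- c(0, f[-1]^(-beta / 2))          # zero the DC bin
    x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
    as.numeric((x - mean(x)) / stats::sd(x))
  })
}

#' Generate an amplitude-modulated oscillation
#'
#' A sinusoid at `osc_freq` whose instantaneous amplitude is a slowly varying
#' strictly positive envelope: a 1/f^`am_beta` process low-pass filtered at
#' `am_cutoff` with a zero-phase 4th-order Butterworth filter, standardized,
#' then mapped to `1 + mod_depth * z` and floored at 0.05 to keep the
#' amplitude physical.
#'
#' @param n_samples series length.
#' @param sampling_rate Hz.
#' @param osc_freq oscillation frequency, Hz (< Nyquist).
#' @param am_beta exponent of the amplitude process.
#' @param am_cutoff low-pass cutoff of the amplitude process, Hz
#'   (< `osc_freq`).
#' @param mod_depth modulation depth; 0 gives a constant-amplitude sinusoid.
#' @param phase carrier phase in radians; `NULL` draws it uniformly.
#' @param seed optional seed.
#' @return list with `signal`, `envelope`, `carrier` (unit sinusoid) and
#'   `phase`.
#' @export
gen_am_oscillation <- function(n_samples, sampling_rate, osc_freq = 10,
                               am_beta = 1, am_cutoff = 1, mod_depth = 0.5,
                               phase = NULL, seed = NULL) {
  if (osc_freq >= sampling_rate / 2) {
    stop_classed("invalid_argument", "osc_freq must be below Nyquist")
  }
  if (am_cutoff >= osc_freq) {
    stop_classed("invalid_argument", "am_cutoff must be below osc_freq")
  }
  n <- as.integer(n_samples)
  t <- (seq_len(n) - 1L) / sampling_rate
  with_seed(seed, {
    if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
    if (mod_depth > 0) {
      z <- gen_powerlaw_noise(n, sampling_rate, am_beta)
      bf <- signal::butter(4, am_cutoff / (sampling_rate / 2), type = "low")
      zf <- signal::filtfilt(bf, z)
      zf <- (zf - mean(zf)) / stats::sd(zf)
      env <- pmax(1 + mod_depth * zf, 0.05)
    } else {
      env <- rep(1, n)
    }
    carrier <- sin(2 * pi * osc_freq * t + phase)
    list(signal = env * carrier, envelope = env, carrier = carrier,
         phase = phase)
  })
}

# Half-sine response lobe evaluated on a time axis (relative to stimulus
# onset): sin(pi * (t - onset)/duration) on [onset, onset + duration), else 0.
response_lobe <- function(time, onset, duration) {
  lobe <- numeric(length(time))
  idx <- which(time >= onset - 1e-9 & time < onset + duration - 1e-9)
  lobe[idx] <- sin(pi * (time[idx] - onset) / duration)
  lobe
}

#' Apply a stimulus-evoked response to a simulated trial
#'
#' Modifies a component-wise trial according to `config$response_kind`:
#' additive kinds add `amplitude * half-sine lobe` to the summed signal
#' (amplitude = `gain * prestim_value` when coupled, `gain * u` with an
#' independent standard-normal `u` when uncoupled); `"desync"` multiplies the
#' oscillation envelope by `1 - desync_depth * lobe`; `"none"` returns the
#' input unchanged. The realized response amplitude is recorded as ground
#' truth (for `"desync"`, the negative peak envelope reduction
#' `-desync_depth`).
#'
#' @param trial list with elements `noise`, `envelope`, `carrier`, and `time`
#'   (seconds relative to onset), as built by [gen_dataset()].
#' @param prestim_value pre-stimulus amplitude driving the coupling.
#' @param config a [sim_config()].
#' @param u optional pre-drawn standard-normal deviate for the uncoupled
#'   amplitude (drawn internally when `NULL`).
#' @return list with `signal` (the summed trial), the modified components,
#'   and `amplitude` (realized response amplitude).
#' @export
apply_evoked_response <- function(trial, prestim_value, config, u = NULL) {
  kind <- config$response_kind
  lobe <- response_lobe(trial$time, config$response_onset,
                        config$response_duration)
  envelope <- trial$envelope
  evoked <- numeric(length(trial$time))
  amplitude <- 0
  if (kind == "additive_coupled") {
    amplitude <- config$response_gain * prestim_value
    evoked <- amplitude * lobe
  } else if (kind == "additive_uncoupled") {
    if (is.null(u)) u <- stats::rnorm(1)
    amplitude <- config$response_gain * u
    evoked <- amplitude * lobe
  } else if (kind == "desync") {
    if (is.null(envelope) || is.null(trial$carrier)) {
      stop_classed("invalid_state",
                   "desync requires a trial with a separable oscillation")
    }
    envelope <- envelope * (1 - config$desync_depth * lobe)
    amplitude <- -config$desync_depth
  }
  signal <- trial$noise + envelope * trial$carrier + evoked
  list(signal = signal, noise = trial$noise, envelope = envelope,
       carrier = trial$carrier, evoked = evoked, time = trial$time,
       amplitude = amplitude)
}

#' Generate a simulated cohort
#'
#' Per subject, `n_trials` trials of colored noise plus an
#' amplitude-modulated oscillation plus the configured evoked response. The
#' noise is scaled per trial so the oscillation-to-noise power ratio equals
#' `snr_base * exp(N(0, snr_trial_sd))`. The pre-stimulus value driving
#' coupled responses is the mean raw (pre-response) signal over
#' `config$prestim_window`. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `simulated_dataset`: list with `epochs` (one
#'   [epochs_set()] per subject) and `ground_truth` (data.frame with one row
#'   per trial: subject, trial, beta, snr, noise_scale, prestim_value,
#'   response amplitude).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs)
  time <- (seq_len(n) - 1L) / fs - config$trial_duration / 2
  pre_idx <- window_index(time, config$prestim_window)
  epochs <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    dat <- array(NA_real_, dim = c(config$n_trials, 1L, n))
    rows <- data.frame(subject = s, trial = seq_len(config$n_trials),
                       beta = NA_real_, snr = NA_real_,
                       noise_scale = NA_real_, prestim_value = NA_real_,
                       amplitude = NA_real_)
    for (j in seq_len(config$n_trials)) {
      res <- with_seed(child_seed(config$seed, s, j), {
        beta <- stats::runif(1, config$beta_range[1], config$beta_range[2])
        noise <- gen_powerlaw_noise(n, fs, beta)
        osc <- gen_am_oscillation(n, fs, osc_freq = config$osc_freq,
                                  am_beta = config$am_beta,
                                  am_cutoff = config$am_cutoff,
                                  mod_depth = config$osc_mod_depth)
        snr <- config$snr_base * exp(stats::rnorm(1, 0, config$snr_trial_sd))
        osc_power <- mean(osc$signal^2)
        noise_scale <- sqrt(osc_power / snr)   # noise has unit power
        trial <- list(noise = noise_scale * noise, envelope = osc$envelope,
                      carrier = osc$carrier, time = time)
        prestim_value <- mean(trial$noise[pre_idx] +
                                osc$signal[pre_idx])
        out <- apply_evoked_response(trial, prestim_value, config)
        list(signal = out$signal, beta = beta, snr = snr,
             noise_scale = noise_scale, prestim_value = prestim_value,
             amplitude = out$amplitude)
      })
      dat[j, 1L, ] <- res$signal
      rows$beta[j] <- res$beta
      rows$snr[j] <- res$snr
      rows$noise_scale[j] <- res$noise_scale
      rows$prestim_value[j] <- res$prestim_value
      rows$amplitude[j] <- res$amplitude
    }
    epochs[[s]] <- epochs_set(dat, time = time, sampling_rate = fs,
                              channel_names = "sim01",
                              subject_id = sprintf("sim%03d", s))
    gt[[s]] <- rows
  }
  structure(list(epochs = epochs, ground_truth = do.call(rbind, gt),
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  d <- dim(x$epochs[[1]]$data)
  cat(sprintf(
    "simulated_dataset: %d subjects x %d trials x %d channel(s) x %d samples (%g Hz, %s response)\n",
    length(x$epochs), d[1], d[2], d[3], x$config$sampling_rate,
    x$config$response_kind))
  invisible(x)
}

#' Build the SNR sweep configuration grid
#'
#' Cartesian grid over base SNR levels and across-trial SNR-variability
#' levels. Each cell holds a positive-control (`additive_coupled`) and a
#' negative-control (`additive_uncoupled`) configuration differing only in
#' `response_kind` and sharing the same seed, so both controls see identical
#' noise realizations. A variability level `v` maps to the log-normal
#' parameter `snr_trial_sd = sqrt(log(1 + v^2))`, i.e. the per-trial SNR
#' multiplier has standard deviation `v` around its unit median scale.
#'
#' @param levels strictly positive base-SNR levels.
#' @param sd_levels strictly positive variability levels (defaults to
#'   `levels`).
#' @param base a [sim_config()] supplying all other parameters.
#' @return data.frame with one row per (cell, control) and a list-column
#'   `config`.
#' @export
gen_snr_grid <- function(levels, sd_levels = levels, base = sim_config()) {
  if (length(levels) == 0 || length(sd_levels) == 0) {
    stop_classed("invalid_argument", "levels must be non-empty")
  }
  if (any(levels <= 0) || any(sd_levels <= 0)) {
    stop_classed("invalid_argument", "levels must be strictly positive")
  }
  cells <- expand.grid(snr_base = levels, snr_var = sd_levels,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", 2L * nrow(cells))
  meta <- vector("list", 2L * nrow(cells))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    for (kind in c("additive_coupled", "additive_uncoupled")) {
      cfg <- base
      cfg$response_kind <- kind
      cfg$snr_base <- cells$snr_base[i]
      cfg$snr_trial_sd <- sqrt(log1p(cells$snr_var[i]^2))
      cfg$seed <- child_seed(base$seed, i)
      k <- k + 1L
      out[[k]] <- cfg
      meta[[k]] <- data.frame(cell = i, snr_base = cells$snr_base[i],
                              snr_var = cells$snr_var[i], kind = kind)
    }
  }
  grid <- do.call(rbind, meta)
  grid$config <- out
  grid
}
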