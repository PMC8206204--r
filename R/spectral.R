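# Time-frequency decomposition, per-subject frequency-band definition, and
# IRASA separation of oscillatory and fractal (scale-free) spectral
# components.

#' Logarithmically spaced wavelet frequencies
#'
#' @param n number of frequencies.
#' @param fmin,fmax range, Hz.
#' @return numeric vector of `n` log-spaced frequencies.
#' @export
log_freqs <- function(n = 50, fmin = 2, fmax = 200) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Morlet wavelet time-frequency power
#'
#' Complex Morlet convolution per trial, channel and frequency; power is the
#' squared magnitude. The wavelet at frequency f has Gaussian SD
#' `n_cycles / (2 pi f)` and is truncated at +/- 3 SD; output samples within
#' one wavelet half-length of the epoch edges are marked `NA` (invalid) so
#' they are excluded from all downstream statistics. The wavelet is scaled
#' so a unit-amplitude sinusoid at f yields power 1 at its own frequency.
#'
#' @param epochs an [epochs_set()].
#' @param freqs frequencies in Hz (all below Nyquist).
#' @param n_cycles number of wavelet cycles (>= 1).
#' @return object of class `tf_representation`: list with `power`
#'   (trials x channels x frequencies x times), `freqs`, `time`,
#'   `sampling_rate`.
#' @export
morlet_tfr <- function(epochs, freqs = log_freqs(), n_cycles = 3) {
  stopifnot(inherits(epochs, "epochs_set"), n_cycles >= 1)
  fs <- epochs$sampling_rate
  if (any(freqs >= fs / 2)) {
    stop_classed("invalid_argument",
                 "all wavelet frequencies must be below Nyquist (%g Hz)", fs / 2)
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop_classed("invalid_argument", "freqs must be strictly increasing")
  }
  d <- dim(epochs$data)
  n <- d[3]
  power <- array(NA_real_, dim = c(d[1], d[2], length(freqs), n))
  # precompute wavelets and their FFTs at a common padded length
  wavelets <- lapply(freqs, function(f) {
    sigma <- n_cycles / (2 * pi * f)
    half <- ceiling(3 * sigma * fs)
    tt <- (-half:half) / fs
    g <- exp(-tt^2 / (2 * sigma^2))
    w <- g * exp(2i * pi * f * tt)
    list(w = w * 2 / sum(g), half = half)
  })
  max_half <- max(vapply(wavelets, `[[`, 0, "half"))
  nfft <- stats::nextn(n + 2L * max_half, 2)
  wf <- lapply(wavelets, function(wl) {
    wpad <- complex(nfft)
    wpad[seq_along(wl$w)] <- wl$w
    stats::fft(wpad)
  })
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      xpad <- complex(nfft)
      xpad[seq_len(n)] <- epochs$data[i, c, ]
      xf <- stats::fft(xpad)
      for (k in seq_along(freqs)) {
        half <- wavelets[[k]]$half
        conv <- stats::fft(xf * Conj(wf[[k]]), inverse = TRUE) / nfft
        # circular cross-correlation: the wavelet center aligned with sample
        # t sits at lag t - half - 1
        est <- Mod(conv[((seq_len(n) - 1L - half) %% nfft) + 1L])^2
        if (half >= 1) {
          est[seq_len(min(half, n))] <- NA_real_
          est[seq.int(max(1L, n - half + 1L), n)] <- NA_real_
        }
        power[i, c, k, ] <- est
      }
    }
  }
  structure(list(power = power, freqs = freqs, time = epochs$time,
                 sampling_rate = fs),
            class = "tf_representation")
}

#' Detect an individual alpha peak in a power spectrum
#'
#' Fits a robust straight line to log power vs log frequency (the 1/f
#' background) and looks for a residual local maximum in the 7-14 Hz search
#' range. A peak is accepted when its residual prominence exceeds
#' `min_prominence` (natural-log units above the background). The alpha band
#' is the peak +/- its fitted half-width at half-prominence, floored at
#' +/- 2 Hz.
#'
#' @param psd power values (> 0).
#' @param freqs frequency axis, Hz; must cover 4-18 Hz.
#' @param search peak search range, Hz.
#' @param min_prominence minimum log-power prominence above the background.
#' @return list with `peak` (Hz) and `band` (length-2 interval), or `NULL`
#'   when no alpha peak stands above the background.
#' @export
detect_alpha_band <- function(psd, freqs, search = c(7, 14),
                              min_prominence = 0.2) {
  psd <- as.numeric(psd)
  if (length(psd) != length(freqs)) {
    stop_classed("invalid_argument", "psd and freqs must have equal length")
  }
  if (any(psd <= 0) || any(!is.finite(psd))) {
    stop_classed("invalid_argument", "psd values must be positive and finite")
  }
  if (min(freqs) > 4 || max(freqs) < 18) {
    stop_classed("invalid_argument", "psd must cover at least 4-18 Hz")
  }
  sel <- freqs >= 4 & freqs <= 18
  lf <- log(freqs[sel]); lp <- log(psd[sel])
  fit <- suppressWarnings(MASS::rlm(lp ~ lf, maxit = 50))
  resid <- lp - stats::predict(fit)
  f_sel <- freqs[sel]
  in_search <- f_sel >= search[1] & f_sel <= search[2]
  if (!any(in_search)) return(NULL)
  r_search <- resid[in_search]
  pk <- which.max(r_search)
  prom <- r_search[pk]
  if (!is.finite(prom) || prom < min_prominence) return(NULL)
  peak_f <- f_sel[in_search][pk]
  # half-width at half prominence, scanning outwards from the peak
  half_level <- prom / 2
  f_all <- f_sel; r_all <- resid
  ipk <- which(f_all == peak_f)[1]
  i_lo <- ipk
  while (i_lo > 1 && r_all[i_lo - 1] > half_level) i_lo <- i_lo - 1
  i_hi <- ipk
  while (i_hi < length(r_all) && r_all[i_hi + 1] > half_level) i_hi <- i_hi + 1
  half_width <- max((f_all[i_hi] - f_all[i_lo]) / 2, 2)
  list(peak = peak_f, band = c(peak_f - half_width, peak_f + half_width))
}

#' Frequency-band scheme
#'
#' Builds the named band intervals used throughout the analysis. Delta is
#' always \[2, 4\] Hz. When an alpha peak is supplied (see
#' [detect_alpha_band()]), theta runs from 4 Hz to the alpha lower edge and
#' beta from the alpha upper edge to 30 Hz, individualizing the scheme per
#' subject; otherwise the standard edges theta \[4, 8\], alpha \[8, 13\],
#' beta \[13, 30\] are used. Low gamma is \[30, 100\] Hz (\[30, 50\] for
#' EEG-style data) and high gamma \[100, 200\] (\[50, 85\] when the scheme is
#' built for IRASA output, which resolves only up to 85 Hz).
#'
#' @param alpha optional result of [detect_alpha_band()].
#' @param modality `"meg"` or `"eeg"` (sets the gamma edges).
#' @param irasa build the gamma bands for the IRASA frequency range.
#' @return named list of length-2 intervals with attribute
#'   `alpha_peak`.
#' @export
band_scheme <- function(alpha = NULL, modality = c("meg", "eeg"),
                        irasa = FALSE) {
  modality <- match.arg(modality)
  if (is.null(alpha)) {
    a_lo <- 8; a_hi <- 13; peak <- NA_real_
  } else {
    a_lo <- max(alpha$band[1], 4.5); a_hi <- min(alpha$band[2], 29)
    peak <- alpha$peak
  }
  lg_hi <- if (irasa) 50 else if (modality == "meg") 100 else 50
  hg <- if (irasa) c(50, 85) else if (modality == "meg") c(100, 200) else NULL
  bands <- list(delta = c(2, 4), theta = c(4, a_lo), alpha = c(a_lo, a_hi),
                beta = c(a_hi, 30), low_gamma = c(30, lg_hi))
  if (!is.null(hg)) bands$high_gamma <- hg
  attr(bands, "alpha_peak") <- peak
  attr(bands, "individualized") <- !is.null(alpha)
  bands
}

#' Band-average power from a time-frequency representation
#'
#' Mean power over the frequencies falling inside the closed band interval,
#' per trial, channel and time. `NA` power values (wavelet edge samples or
#' missing oscillatory estimates) propagate as `NA` when all in-band values
#' are missing, and are excluded pairwise otherwise.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param band length-2 frequency interval, Hz.
#' @return trials x channels x times array.
#' @export
band_power <- function(tfr, band) {
  stopifnot(inherits(tfr, "tf_representation"), length(band) == 2L)
  sel <- which(tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9)
  if (length(sel) == 0L) {
    stop_classed("invalid_argument",
                 "band [%g, %g] Hz contains none of the estimated frequencies",
                 band[1], band[2])
  }
  out <- apply(tfr$power[, , sel, , drop = FALSE], c(1, 2, 4), mean,
               na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# Hann-tapered one-sided periodogram; returns freqs and power density.
# With `prewhiten`, the series is first-differenced before tapering and the
# density re-colored by the differencer's transfer function 4 sin^2(pi f/fs):
# steep (1/f^beta) spectra otherwise leak low-frequency power across the
# Hann main lobe and bias the lowest analyzed frequencies upward.
hann_periodogram <- function(x, fs, prewhiten = FALSE) {
  if (prewhiten) x <- diff(x)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  half <- floor(n / 2)
  p <- (Mod(X[seq_len(half + 1)])^2) / (fs * sum(w^2))
  p[2:half] <- 2 * p[2:half]
  freqs <- (0:half) * fs / n
  if (prewhiten) {
    tf <- 4 * sin(pi * freqs / fs)^2
    tf[1] <- Inf                       # DC is unrecoverable after differencing
    p <- p / tf
  }
  list(freqs = freqs, power = p)
}

#' IRASA configuration
#'
#' @param hset resampling factors; default 1.1 to 2.9 in steps of 0.05,
#'   excluding 2 (an integer factor would alias oscillatory peaks onto
#'   themselves).
#' @param window sliding-window length, seconds.
#' @param step sliding-window step, seconds.
#' @param freq_range analyzed frequency range, Hz.
#' @return object of class `irasa_config`.
#' @export
irasa_config <- function(hset = setdiff(seq(1.1, 2.9, by = 0.05), 2),
                         window = 1.5, step = 0.02, freq_range = c(2, 85)) {
  hset <- round(hset, 10)
  if (any(abs(hset - 2) < 1e-9)) {
    stop_classed("invalid_argument", "hset must exclude the factor 2")
  }
  if (any(hset <= 1)) {
    stop_classed("invalid_argument", "all resampling factors must exceed 1")
  }
  structure(list(hset = hset, window = window, step = step,
                 freq_range = freq_range), class = "irasa_config")
}

# Rational p/q approximation of a resampling factor (exact for the default
# hset, whose members are multiples of 1/20).
rational_factor <- function(h, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- round(h * q)
    if (abs(p / q - h) < 1e-9) return(c(p, q))
  }
  stop("no rational approximation for factor ", h)
}

#' IRASA separation of a signal segment into fractal and oscillatory spectra
#'
#' For each resampling factor h, the segment is resampled by h and by 1/h
#' (polyphase rational resampling), the Hann-tapered periodogram of each is
#' computed, and the geometric mean of the pair taken; the median of these
#' geometric means across the factor set is the fractal (scale-free)
#' spectrum. The oscillatory spectrum is the mixed spectrum minus the
#' fractal spectrum and may be negative where the median overshoots; such
#' values are the caller's to treat as missing.
#'
#' @param segment numeric vector, or channels x time matrix.
#' @param sampling_rate Hz.
#' @param config an [irasa_config()].
#' @return list with `freqs` and (per channel) matrices `mixed`, `fractal`,
#'   `oscillatory` (channels x frequencies; vectors for vector input).
#' @export
irasa <- function(segment, sampling_rate, config = irasa_config()) {
  vec_in <- is.null(dim(segment))
  x <- if (vec_in) matrix(segment, nrow = 1) else as.matrix(segment)
  n <- ncol(x)
  if (n < round(config$window * sampling_rate)) {
    stop_classed("window_error",
                 "segment (%d samples) shorter than the IRASA window (%d)",
                 n, round(config$window * sampling_rate))
  }
  base <- hann_periodogram(x[1, ], sampling_rate)
  keep <- base$freqs >= config$freq_range[1] &
    base$freqs <= config$freq_range[2]
  freqs <- base$freqs[keep]
  pq <- lapply(config$hset, rational_factor)
  nh <- length(config$hset)
  # contiguous groups of resampling factors: within-group averaging of the
  # geometric-mean spectra tames the chi^2 scatter of single periodograms
  # (which would bias a plain median low), while the across-group median
  # still rejects oscillatory peaks, which any one h shifts into a narrow
  # factor run (hence into few groups)
  n_grp <- max(1L, min(6L, nh %/% 4L))
  grp <- cut(seq_len(nh), n_grp, labels = FALSE)
  nch <- nrow(x)
  mixed <- fractal <- matrix(NA_real_, nch, length(freqs))
  tt <- seq_len(n)
  for (c in seq_len(nch)) {
    xi <- x[c, ]
    # linear detrend: the slow 1/f wander otherwise leaves large offsets at
    # the segment edges that excite resampling-filter transients
    cf <- stats::lm.fit(cbind(1, tt), xi)$coefficients
    xi <- xi - cf[1] - cf[2] * tt
    mix <- hann_periodogram(xi, sampling_rate, prewhiten = TRUE)
    mixed[c, ] <- mix$power[keep]
    up <- dn <- matrix(NA_real_, nh, length(freqs))
    for (k in seq_len(nh)) {
      p <- pq[[k]][1]; q <- pq[[k]][2]
      xu <- signal::resample(xi, p, q)   # upsampled by h
      xd <- signal::resample(xi, q, p)   # downsampled by h
      # interpret both at the ORIGINAL rate: spectral content shifts by
      # 1/h (upsampled) and h (downsampled); a 1/f^beta spectrum gains
      # factors h^-beta and h^+beta whose geometric mean restores it, while
      # oscillatory peaks land at f0/h and f0*h and are removed by the
      # median across the factor set
      pu <- hann_periodogram(xu, sampling_rate, prewhiten = TRUE)
      pd <- hann_periodogram(xd, sampling_rate, prewhiten = TRUE)
      up[k, ] <- stats::approx(pu$freqs, pu$power, xout = freqs, rule = 2)$y
      d_ <- stats::approx(pd$freqs, pd$power, xout = freqs, rule = 2)$y
      # the downsampled series resolves only interpreted frequencies above
      # ~2 of its own bins; below that its windowed spectrum is attenuated
      d_[freqs < 2 * pd$freqs[2]] <- NA_real_
      dn[k, ] <- d_
    }
    # within each group, average the up- and down-shifted spectra first
    # (debiasing the chi^2 scatter), then take the geometric mean of the
    # pair of group means
    gm <- matrix(NA_real_, n_grp, length(freqs))
    for (gi in seq_len(n_grp)) {
      su_bar <- colMeans(up[grp == gi, , drop = FALSE], na.rm = TRUE)
      sd_bar <- colMeans(dn[grp == gi, , drop = FALSE], na.rm = TRUE)
      gm[gi, ] <- sqrt(su_bar * sd_bar)
    }
    frac <- apply(gm, 2, stats::median, na.rm = TRUE)
    # robust scale matching: the periodogram and the median-of-geometric-
    # means carry slightly different multiplicative estimator biases; the
    # median ratio across the analyzed range (insensitive to localized
    # oscillatory peaks) aligns the fractal level with the mixed spectrum
    # so the oscillatory residual is centred on zero for scale-free input
    # the per-bin ratio of a (chi^2_2-distributed) periodogram to the smooth
    # fractal estimate has median ln(2) x its mean, so the robust median
    # ratio is corrected by that quantile factor
    frac <- frac * stats::median(mixed[c, ] / frac, na.rm = TRUE) / log(2)
    fractal[c, ] <- frac
  }
  osc <- mixed - fractal
  if (vec_in) {
    list(freqs = freqs, mixed = mixed[1, ], fractal = fractal[1, ],
         oscillatory = osc[1, ])
  } else {
    list(freqs = freqs, mixed = mixed, fractal = fractal, oscillatory = osc)
  }
}

#' Fit the fractal spectrum with a power law
#'
#' Least-squares line through (log f, log P) after resampling the spectrum
#' to points equally spaced in log frequency (so the denser high-frequency
#' end does not dominate the fit). The scaling exponent is the negative
#' slope; the broadband offset is the exponentiated intercept (natural log
#' on both axes), i.e. the fitted power at 1 Hz.
#'
#' @param psd positive power values.
#' @param freqs frequency axis, Hz.
#' @param freq_range fit range, Hz.
#' @return list with `beta` (scaling exponent) and `offset`
#'   (broadband offset, power units, > 0).
#' @export
fit_fractal <- function(psd, freqs, freq_range = c(2, 85)) {
  sel <- freqs >= freq_range[1] & freqs <= freq_range[2] & freqs > 0
  f <- freqs[sel]; p <- psd[sel]
  if (length(f) < 3) {
    stop_classed("invalid_argument", "need at least 3 frequencies in range")
  }
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop_classed("invalid_argument", "psd must be positive over the fit range")
  }
  lgrid <- seq(log(min(f)), log(max(f)), length.out = length(f))
  lp <- stats::approx(log(f), log(p), xout = lgrid)$y
  fit <- stats::lm.fit(cbind(1, lgrid), lp)
  list(beta = -unname(fit$coefficients[2]),
       offset = exp(unname(fit$coefficients[1])))
}

#' Time-resolved IRASA over epochs
#'
#' Runs [irasa()] in a sliding window (centered convention: the output at
#' time t uses samples in `[t - window/2, t + window/2)`), then summarizes
#' each window with [fit_fractal()] and band-mean oscillatory/fractal power.
#' Negative oscillatory power is propagated as missing (`NA`) in the band
#' summaries.
#'
#' @param epochs an [epochs_set()].
#' @param config an [irasa_config()].
#' @param out_times output time axis (seconds); default
#'   `seq(-0.1, 0.8, by = config$step)`.
#' @param bands named list of band intervals (see [band_scheme()]); `NULL`
#'   skips band summaries.
#' @return list with `time`, `freqs`, arrays `beta` and `offset`
#'   (trials x channels x times), and `osc_band` / `frac_band`
#'   (trials x channels x bands x times) when `bands` is given.
#' @export
irasa_sliding <- function(epochs, config = irasa_config(),
                          out_times = NULL, bands = NULL) {
  stopifnot(inherits(epochs, "epochs_set"))
  fs <- epochs$sampling_rate
  if (is.null(out_times)) out_times <- seq(-0.1, 0.8, by = config$step)
  half <- config$window / 2
  d <- dim(epochs$data)
  nt <- length(out_times)
  beta <- offset <- array(NA_real_, dim = c(d[1], d[2], nt))
  nb <- if (is.null(bands)) 0L else length(bands)
  osc_band <- frac_band <- if (nb > 0) {
    array(NA_real_, dim = c(d[1], d[2], nb, nt))
  } else NULL
  win_n <- round(config$window * fs)
  for (ti in seq_len(nt)) {
    t0 <- out_times[ti] - half
    i0 <- which.min(abs(epochs$time - t0))
    if (epochs$time[i0] > t0 + 1e-9) i0 <- i0 - 1L
    if (i0 < 1L || i0 + win_n - 1L > d[3]) {
      stop_classed("window_error",
                   "epoch does not cover the IRASA window centred at %.3f s",
                   out_times[ti])
    }
    idx <- i0:(i0 + win_n - 1L)
    for (i in seq_len(d[1])) {
      res <- irasa(epochs$data[i, , idx, drop = TRUE], fs, config)
      frac <- if (d[2] == 1) rbind(res$fractal) else res$fractal
      mix <- if (d[2] == 1) rbind(res$mixed) else res$mixed
      osc <- if (d[2] == 1) rbind(res$oscillatory) else res$oscillatory
      for (c in seq_len(d[2])) {
        ft <- fit_fractal(frac[c, ], res$freqs, config$freq_range)
        beta[i, c, ti] <- ft$beta
        offset[i, c, ti] <- ft$offset
        if (nb > 0) {
          for (b in seq_len(nb)) {
            fsel <- res$freqs >= bands[[b]][1] & res$freqs <= bands[[b]][2]
            if (!any(fsel)) next
            ov <- osc[c, fsel]
            ov[ov < 0] <- NA_real_   # negative oscillatory power -> missing
            osc_band[i, c, b, ti] <-
              if (all(is.na(ov))) NA_real_ else mean(ov, na.rm = TRUE)
            frac_band[i, c, b, ti] <- mean(frac[c, fsel])
          }
        }
      }
    }
  }
  out <- list(time = out_times, beta = beta, offset = offset,
              osc_band = osc_band, frac_band = frac_band,
              bands = if (nb > 0) names(bands) else NULL)
  out
}
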