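# Independent oracles and small fixture builders used across the suite.

# Spectral-slope oracle: smoothed periodogram (Daniell) log-log fit over a
# frequency range; independent of the generator's spectral-domain shaping.
welch_slope <- function(x, fs, frange = c(2, 100)) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 15,
                          taper = 0.1, plot = FALSE, detrend = TRUE)
  sel <- sp$freq >= frange[1] & sp$freq <= frange[2]
  unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
}

# Exact two-sided signed-rank p by full sign enumeration (small n).
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wall <- as.vector(signs %*% r)
  mean(abs(wall - mu) >= abs(obs - mu) - 1e-12)
}

# Exhaustive sign-flip cluster permutation oracle for one channel and tiny n:
# enumerates all 2^n condition swaps, using plain wilcox-style z and run
# clustering written independently of the package internals.
exact_cluster_p <- function(d, cluster_alpha = 0.05) {
  n <- nrow(d)
  zfun <- function(dm) {
    apply(dm, 2, function(col) {
      col <- col[col != 0]
      m <- length(col)
      if (m == 0) return(0)
      r <- rank(abs(col))
      w <- sum(r[col > 0])
      mu <- m * (m + 1) / 4
      tie_tab <- table(r)
      sg <- sqrt(m * (m + 1) * (2 * m + 1) / 24 -
                   sum(tie_tab^3 - tie_tab) / 48)
      if (sg == 0) return(0)
      # continuity-corrected normal approximation, as in wilcox.test
      sign(w - mu) * max(abs(w - mu) - 0.5, 0) / sg
    })
  }
  thr <- stats::qnorm(1 - cluster_alpha / 2)
  massfun <- function(z) {
    best <- 0
    for (sgn in c(1, -1)) {
      m <- if (sgn > 0) z > thr else z < -thr
      rl <- rle(m)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
      for (i in which(rl$values)) {
        best <- max(best, abs(sum(z[starts[i]:ends[i]])))
      }
    }
    best
  }
  obs <- massfun(zfun(d))
  if (obs == 0) return(1)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(flips, 1, function(f) massfun(zfun(d * f)))
  min(1, 2 * mean(null_max >= obs - 1e-12))
}

# Small epochs fixture: stationary noise, 2+ channels, spans [-1, 1) s.
make_noise_epochs <- function(n_trials = 8, n_chan = 1, fs = 250,
                              span = c(-1, 1), seed = 1) {
  set.seed(seed)
  n <- round((span[2] - span[1]) * fs)
  dat <- array(stats::rnorm(n_trials * n_chan * n),
               c(n_trials, n_chan, n))
  epochs_set(dat, time = span[1] + (0:(n - 1)) / fs, sampling_rate = fs,
             subject_id = "fix")
}
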