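# The two estimators of spontaneous-evoked correlation.
#
# Pseudotrial method: trials are median-split by pre-stimulus amplitude,
# separately for real trials and stimulus-free pseudotrials; pseudotrial
# group time courses are subtracted from the matching real-trial group time
# courses, correcting for regression to the mean, and the corrected
# high-minus-low difference indexes the correlation (positive difference =
# positive correlation).
#
# TTV method: the across-trial standard deviation of the signal, expressed
# as percent change from its pre-stimulus mean. By the law of total variance
# (sigma_{X+Y}^2 = sigma_X^2 + sigma_Y^2 + 2 r sigma_X sigma_Y), a
# post-stimulus TTV decrease can only arise from negative spontaneous-evoked
# correlation.

#' Median split of trials by pre-stimulus amplitude
#'
#' Trials are stably sorted by value (ties broken by trial index); the top
#' half goes to `"high"`, the bottom half to `"low"`. With an odd number of
#' trials the middle trial goes to `"low"`, so the group sizes never differ
#' by more than one.
#'
#' @param values per-trial pre-stimulus amplitudes (finite).
#' @return factor of `"low"`/`"high"` labels, one per trial.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) {
    stop_classed("invalid_argument", "median split needs at least 2 trials")
  }
  if (any(!is.finite(values))) {
    stop_classed("invalid_argument",
                 "median split requires finite prestimulus values")
  }
  ord <- order(values, seq_along(values))   # stable: ties by trial index
  n <- length(values)
  n_high <- n %/% 2                          # odd count: middle trial -> low
  labels <- rep("low", n)
  labels[ord[(n - n_high + 1L):n]] <- "high"
  factor(labels, levels = c("low", "high"))
}

#' Percent change from a baseline
#'
#' `100 * (x - baseline) / baseline`, broadcasting a per-channel baseline
#' over trials and time. Intended for power-like signals whose baseline is
#' strictly positive; time-domain signals (baseline approximately zero) must
#' skip this normalization.
#'
#' @param x trials x channels x times array (or matrix / vector).
#' @param baseline per-channel positive scalars.
#' @return array of `x`'s shape, in percent units.
#' @export
percent_change <- function(x, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop_classed("invalid_argument",
                 "baseline must be strictly positive (time-domain signals are not normalized)")
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(length(baseline) %in% c(1L, dim(x)[2]))
    b <- if (length(baseline) == 1L) rep(baseline, dim(x)[2]) else baseline
    out <- x
    for (c in seq_len(dim(x)[2])) {
      out[, c, ] <- 100 * (x[, c, ] - b[c]) / b[c]
    }
    out
  } else {
    stopifnot(length(baseline) == 1L)
    100 * (x - baseline) / baseline
  }
}

#' Pseudotrial correction of median-split group time courses
#'
#' Subtracts the pseudotrial group means from the matching real-trial group
#' means (high from high, low from low) and forms the corrected
#' high-minus-low difference. Pseudotrial time courses must already be
#' re-aligned so the pseudotrial onset maps to time 0.
#'
#' @param real_high,real_low,pseudo_high,pseudo_low channels x time group
#'   mean matrices on a common post-onset time axis.
#' @return object of class `corrected_timecourses`: list with
#'   `corrected_high`, `corrected_low`, `difference`.
#' @export
pseudotrial_correct <- function(real_high, real_low, pseudo_high,
                                pseudo_low) {
  dims <- lapply(list(real_high, real_low, pseudo_high, pseudo_low), dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop_classed("invalid_argument",
                 "all four group time courses must share one shape")
  }
  ch <- real_high - pseudo_high
  cl <- real_low - pseudo_low
  structure(list(corrected_high = ch, corrected_low = cl,
                 difference = ch - cl),
            class = "corrected_timecourses")
}

#' Trial-to-trial variability time course
#'
#' Across-trial sample standard deviation (n - 1 denominator) at each
#' channel and time point, normalized to its mean over the pre-stimulus
#' window and expressed in percent change. Missing samples are excluded
#' pairwise.
#'
#' @param x trials x channels x times array.
#' @param time time axis, seconds.
#' @param prestim_window baseline window (half-open interval), seconds.
#' @return channels x times matrix of percent-change TTV (class
#'   `ttv_timecourse`, with attribute `sd` holding the raw SD course).
#' @export
ttv <- function(x, time, prestim_window = c(-0.1, 0)) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[1] >= 2L)
  sd_tc <- apply(x, c(2, 3), stats::sd, na.rm = TRUE)
  base_idx <- window_index(time, prestim_window)
  if (length(base_idx) == 0L) {
    stop_classed("window_error", "prestimulus window contains no samples")
  }
  base <- rowMeans(sd_tc[, base_idx, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop_classed("degenerate_baseline",
                 "across-trial SD is zero (or undefined) in the prestimulus window")
  }
  out <- 100 * sweep(sd_tc, 1, base, "-") / base
  structure(out, sd = sd_tc, baseline = base, time = time,
            class = c("ttv_timecourse", class(out)))
}

#' Sample decomposition of the variance of a sum
#'
#' Computes the standard deviations of two per-trial components, their
#' correlation, and the SD of their sum, which satisfy the law-of-total-
#' variance identity
#' `sigma_{X+Y}^2 = sigma_X^2 + sigma_Y^2 + 2 r sigma_X sigma_Y` exactly in
#' the sample. Used as the analytic oracle behind the TTV method's
#' interpretation: a variance reduction after adding Y requires r < 0.
#'
#' @param X,Y per-trial scalars (>= 3 trials, nonzero variance).
#' @return list with `sigma_X`, `sigma_Y`, `r_XY`, `sigma_total`.
#' @export
total_variance_oracle <- function(X, Y) {
  if (length(X) < 3L || length(Y) != length(X)) {
    stop_classed("invalid_argument", "need >= 3 paired trials")
  }
  sx <- stats::sd(X); sy <- stats::sd(Y)
  if (sx == 0 || sy == 0) {
    stop_classed("invalid_argument", "X and Y must have nonzero variance")
  }
  list(sigma_X = sx, sigma_Y = sy, r_XY = stats::cor(X, Y),
       sigma_total = stats::sd(X + Y))
}

#' Signed-area summary index within a cluster mask
#'
#' Per channel, the signed sum of the time course over the in-mask time
#' points multiplied by the sample step: the area under the curve of the
#' effect across the significant cluster. Channels whose mask is empty get
#' `NA`.
#'
#' @param timecourse channels x time matrix (e.g. the corrected
#'   high-minus-low difference, or the TTV course).
#' @param cluster_mask channels x time logical matrix.
#' @param dt sample step, seconds.
#' @return per-channel numeric vector.
#' @export
summary_index <- function(timecourse, cluster_mask, dt) {
  timecourse <- rbind(timecourse)
  cluster_mask <- rbind(cluster_mask)
  stopifnot(all(dim(cluster_mask) == dim(timecourse)))
  out <- vapply(seq_len(nrow(timecourse)), function(c) {
    m <- cluster_mask[c, ]
    if (!any(m)) return(NA_real_)
    sum(timecourse[c, m]) * dt
  }, 0)
  names(out) <- rownames(timecourse)
  out
}

#' Per-subject spontaneous-evoked correlation estimates
#'
#' Runs the full single-subject chain of both estimators on a signal array:
#' per-channel pre-stimulus values for real trials and pseudotrials, separate
#' median splits, optional percent-change normalization (power-like signals
#' only, each trial kind normalized by the mean over its own pre-stimulus
#' windows), pseudotrial-corrected group time courses, and the TTV course.
#'
#' @param x trials x channels x times signal array (raw signal, band power,
#'   or a scale-free parameter course), or an [epochs_set()].
#' @param time time axis (ignored when `x` is an `epochs_set`).
#' @param windows a [window_spec()].
#' @param power logical: treat the signal as power-like (non-negative) and
#'   apply percent-change normalization.
#' @param trials optional [define_trials()] table (built with default
#'   placement when `NULL`).
#' @param seed seed for random pseudotrial placement.
#' @return list with `corrected` ([pseudotrial_correct()] output on the
#'   post-onset axis `resp_time`), `ttv_post` (channels x time TTV percent
#'   change over the response window), `ttv_full` (the whole-epoch course),
#'   `split` (real/pseudo labels), and `resp_time`.
#' @export
sec_estimate <- function(x, time = NULL, windows = window_spec(),
                         power = FALSE, trials = NULL, seed = NULL) {
  if (inherits(x, "epochs_set")) {
    time <- x$time
    fs <- x$sampling_rate
    if (is.null(trials)) {
      trials <- define_trials(x, windows, seed = seed)
    }
    x <- x$data
  } else {
    stopifnot(!is.null(time))
    fs <- 1 / check_time_axis(time)
    if (is.null(trials)) {
      # synthesize a table from the windows (fixed pseudotrial placement)
      dummy <- structure(list(data = x, time = time, sampling_rate = fs),
                         class = "epochs_set")
      trials <- define_trials(dummy, windows, seed = seed)
    }
  }
  real <- trials[trials$kind == "real", , drop = FALSE]
  pseudo <- trials[trials$kind == "pseudo", , drop = FALSE]
  n_resp <- length(window_index(time, windows$poststim))
  resp_time <- time[window_index(time, windows$poststim)]
  n_chan <- dim(x)[2]

  extract <- function(tab, what = c("resp", "prestim")) {
    what <- match.arg(what)
    arr <- if (what == "resp") {
      array(NA_real_, dim = c(nrow(tab), n_chan, n_resp))
    } else NULL
    pre_vals <- matrix(NA_real_, nrow(tab), n_chan)
    for (r in seq_len(nrow(tab))) {
      if (what == "resp") {
        idx <- window_index(time, c(tab$resp_start[r], tab$resp_end[r]))
        idx <- idx[seq_len(min(length(idx), n_resp))]
        arr[r, , ] <- x[tab$epoch[r], , idx]
      } else {
        idx <- window_index(time, c(tab$prestim_start[r], tab$prestim_end[r]))
        pre_vals[r, ] <- apply(x[tab$epoch[r], , idx, drop = FALSE], 2,
                               mean, na.rm = TRUE)
      }
    }
    if (what == "resp") arr else pre_vals
  }

  pre_real <- extract(real, "prestim")
  pre_pseudo <- extract(pseudo, "prestim")
  resp_real <- extract(real, "resp")
  resp_pseudo <- extract(pseudo, "resp")

  if (power) {
    # normalize each trial kind by the mean over its own prestim windows
    b_real <- colMeans(pre_real, na.rm = TRUE)
    b_pseudo <- colMeans(pre_pseudo, na.rm = TRUE)
    resp_real <- percent_change(resp_real, b_real)
    resp_pseudo <- percent_change(resp_pseudo, b_pseudo)
  }

  group_mean <- function(resp, labels_by_chan, grp) {
    out <- matrix(NA_real_, n_chan, n_resp)
    for (c in seq_len(n_chan)) {
      sel <- labels_by_chan[[c]] == grp
      m <- matrix(resp[sel, c, , drop = FALSE], nrow = sum(sel))
      out[c, ] <- colMeans(m, na.rm = TRUE)
    }
    out
  }
  split_real <- lapply(seq_len(n_chan),
                       function(c) median_split(pre_real[, c]))
  split_pseudo <- lapply(seq_len(n_chan),
                         function(c) median_split(pre_pseudo[, c]))
  corrected <- pseudotrial_correct(
    group_mean(resp_real, split_real, "high"),
    group_mean(resp_real, split_real, "low"),
    group_mean(resp_pseudo, split_pseudo, "high"),
    group_mean(resp_pseudo, split_pseudo, "low"))

  signal_for_ttv <- if (power) {
    b_all <- colMeans(pre_real, na.rm = TRUE)
    percent_change(x, b_all)
  } else x
  ttv_full <- ttv(signal_for_ttv, time, windows$prestim)
  ttv_post <- ttv_full[, window_index(time, windows$poststim), drop = FALSE]

  list(corrected = corrected, ttv_post = ttv_post, ttv_full = ttv_full,
       split = list(real = split_real, pseudo = split_pseudo),
       prestim = list(real = pre_real, pseudo = pre_pseudo),
       resp_time = resp_time, windows = windows)
}
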