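# Epoched-data container and the definition of real trials, pseudotrials,
# and their pre-stimulus windows. All windows are half-open [start, end) with
# the stimulus-onset sample (t == 0) belonging to the post-stimulus window.

#' Epoched multi-channel recording
#'
#' Container for a per-subject set of epochs: a trials x channels x samples
#' array with a uniform time axis relative to stimulus onset. The time axis
#' must cover at least the analyzed span \[-1.0, +0.8\] s.
#'
#' @param data numeric array, trials x channels x samples (a matrix is
#'   treated as trials x samples with one channel).
#' @param time time axis in seconds relative to stimulus onset (length =
#'   number of samples); alternatively `NULL` to derive it from
#'   `sampling_rate` and `tmin`.
#' @param sampling_rate sampling rate, Hz.
#' @param channel_names character vector of channel labels.
#' @param channel_positions optional channels x 2 matrix of 2-D layout
#'   coordinates (used for spatial clustering).
#' @param subject_id subject label.
#' @param tmin epoch start time, used only when `time` is `NULL`.
#' @return object of class `epochs_set`.
#' @export
epochs_set <- function(data, time = NULL, sampling_rate,
                       channel_names = NULL, channel_positions = NULL,
                       subject_id = "S01", tmin = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1L, ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_trials <- dim(data)[1]; n_chan <- dim(data)[2]; n_samp <- dim(data)[3]
  if (n_trials < 2L) {
    stop_classed("invalid_argument", "an epochs_set needs at least 2 trials")
  }
  if (is.null(time)) {
    if (is.null(tmin)) stop("either time or tmin must be given")
    time <- tmin + (seq_len(n_samp) - 1L) / sampling_rate
  }
  stopifnot(length(time) == n_samp)
  dt <- check_time_axis(time)
  if (abs(dt - 1 / sampling_rate) > 1e-6 / sampling_rate) {
    stop_classed("format_error",
                 "time-axis step (%g s) does not match sampling_rate (%g Hz)",
                 dt, sampling_rate)
  }
  if (time[1] > -1.0 + 1e-9 || time[n_samp] < 0.8 - dt - 1e-9) {
    stop_classed("window_error",
                 "epochs must cover at least [-1.0, 0.8] s around onset; got [%.3f, %.3f]",
                 time[1], time[n_samp])
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(n_chan))
  }
  stopifnot(length(channel_names) == n_chan)
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    stopifnot(nrow(channel_positions) == n_chan,
              ncol(channel_positions) == 2L)
  }
  structure(list(data = data, time = as.numeric(time),
                 sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 channel_positions = channel_positions,
                 subject_id = as.character(subject_id)),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epochs_set '%s': %d trials x %d channels x %d samples, %g Hz, t in [%.3f, %.3f] s\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate,
              x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' Analysis window specification
#'
#' Defines the pre-stimulus and response windows of real trials and
#' pseudotrials. Defaults: real pre-stimulus \[-0.1, 0) s, response
#' \[0, 0.8) s; pseudotrial response \[-0.9, -0.1) s with its own
#' "pre-stimulus" \[-1.0, -0.9) s. The `prestim_length` control (0.05, 0.1,
#' or 0.2 s) rescales both pre-stimulus windows together, keeping them equal
#' in length; pseudo windows always precede, and never overlap, the real
#' pre-stimulus window.
#'
#' @param prestim_length pre-stimulus window length in seconds (one of 0.05,
#'   0.1, 0.2).
#' @param poststim_end end of the response window, seconds.
#' @param pseudo_onset pseudotrial onset time, seconds (response window is
#'   `[pseudo_onset, pseudo_onset + poststim_end)`). By default the
#'   pseudotrial response ends exactly where the real pre-stimulus window
#'   begins, i.e. `-(prestim_length + poststim_end)`, which reproduces the
#'   -0.9 s onset for the standard 100 ms pre-stimulus window.
#' @param random_pseudo_placement place the pseudotrial window uniformly at
#'   random within the eligible pre-onset span instead of at `pseudo_onset`
#'   (used to control for anticipation effects in long inter-trial
#'   intervals).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(prestim_length = 0.1, poststim_end = 0.8,
                        pseudo_onset = NULL,
                        random_pseudo_placement = FALSE) {
  if (!prestim_length %in% c(0.05, 0.1, 0.2)) {
    stop_classed("invalid_argument",
                 "prestim_length must be one of 0.05, 0.1, 0.2 seconds")
  }
  stopifnot(poststim_end > 0)
  if (is.null(pseudo_onset)) {
    pseudo_onset <- -(prestim_length + poststim_end)
  }
  r9 <- function(x) round(x, 9)
  ws <- structure(list(
    prestim = r9(c(-prestim_length, 0)),
    poststim = r9(c(0, poststim_end)),
    pseudo_trial = r9(c(pseudo_onset, pseudo_onset + poststim_end)),
    pseudo_prestim = r9(c(pseudo_onset - prestim_length, pseudo_onset)),
    prestim_length = prestim_length,
    random_pseudo_placement = isTRUE(random_pseudo_placement)
  ), class = "window_spec")
  if (ws$pseudo_trial[2] > ws$prestim[1] + 1e-9) {
    stop_classed("invalid_argument",
                 "pseudotrial window must end at or before the real pre-stimulus window")
  }
  ws
}

#' Define real trials and pseudotrials
#'
#' For each epoch, one real trial (pre-stimulus and response windows from
#' `windows`) and one matched pseudotrial carved from the stimulus-free part
#' of the same epoch. With `random_pseudo_placement`, the pseudotrial onset
#' is drawn uniformly (per epoch, seeded) from the span where the full
#' pseudotrial plus its pre-stimulus window fits between the epoch start and
#' the real pre-stimulus window.
#'
#' @param epochs an [epochs_set()].
#' @param windows a [window_spec()].
#' @param seed seed for random pseudotrial placement.
#' @return data.frame (class `trial_table`) with one row per trial: `epoch`,
#'   `kind` (`"real"`/`"pseudo"`), the pre-stimulus and response window
#'   edges, and `offset` (the time mapped to 0 when aligning the response).
#' @export
define_trials <- function(epochs, windows = window_spec(), seed = NULL) {
  stopifnot(inherits(epochs, "epochs_set"), inherits(windows, "window_spec"))
  t0 <- epochs$time[1]
  dt <- 1 / epochs$sampling_rate
  t_end <- epochs$time[length(epochs$time)] + dt
  need_lo <- min(windows$pseudo_prestim[1], windows$prestim[1])
  if (t0 > need_lo + 1e-9 || t_end < windows$poststim[2] - 1e-9) {
    stop_classed("window_error",
                 "epochs [%.3f, %.3f] s do not cover the analysis windows [%.3f, %.3f] s",
                 t0, t_end, need_lo, windows$poststim[2])
  }
  n_ep <- dim(epochs$data)[1]
  dur <- diff(windows$poststim)
  L <- windows$prestim_length
  if (windows$random_pseudo_placement) {
    # eligible onsets o: [o - L, o + dur) fully before the real prestim window
    lo <- t0 + L
    hi <- windows$prestim[1] - dur
    if (hi < lo) {
      stop_classed("window_error",
                   "epoch too short for random pseudotrial placement")
    }
    onsets <- with_seed(seed, stats::runif(n_ep, lo, hi))
    # snap to the sample grid so windows align with samples
    onsets <- t0 + round((onsets - t0) / dt) * dt
  } else {
    onsets <- rep(windows$pseudo_trial[1], n_ep)
  }
  real <- data.frame(epoch = seq_len(n_ep), kind = "real",
                     prestim_start = windows$prestim[1],
                     prestim_end = windows$prestim[2],
                     resp_start = windows$poststim[1],
                     resp_end = windows$poststim[2],
                     offset = windows$poststim[1])
  pseudo <- data.frame(epoch = seq_len(n_ep), kind = "pseudo",
                       prestim_start = onsets - L, prestim_end = onsets,
                       resp_start = onsets, resp_end = onsets + dur,
                       offset = onsets)
  tab <- rbind(real, pseudo)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Mean pre-stimulus amplitude per trial and channel
#'
#' Arithmetic mean over the samples inside a half-open window, per trial and
#' channel. Signed for time-domain input; non-negative for power input.
#' Missing samples (e.g. negative oscillatory power flagged as `NA`) are
#' excluded pairwise.
#'
#' @param data trials x channels x samples array (or an [epochs_set()]).
#' @param window length-2 interval in seconds, half-open.
#' @param time time axis (taken from the `epochs_set` when `data` is one).
#' @return trials x channels matrix.
#' @export
prestim_amplitude <- function(data, window, time = NULL) {
  if (inherits(data, "epochs_set")) {
    time <- data$time
    data <- data$data
  }
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(time) == dim(data)[3])
  idx <- window_index(time, window)
  if (length(idx) == 0L) {
    stop_classed("window_error", "window [%g, %g) contains no samples",
                 window[1], window[2])
  }
  out <- apply(data[, , idx, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
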