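# End-to-end orchestration: the two-simulation discrepancy experiment, the
# additive/non-additive SNR sweep, and the full spontaneous-evoked
# correlation analysis over any collection of epochs. A master seed fans out
# to per-stage seeds via child_seed() so adding stages never perturbs
# earlier random streams.

# Per-subject estimates stacked into group arrays for the two estimators.
collect_subjects <- function(epochs_list, windows, power = FALSE,
                             signal_fun = NULL, seed = NULL) {
  n_sub <- length(epochs_list)
  diffs <- ttvs <- NULL
  summaries <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ep <- epochs_list[[s]]
    if (!is.null(signal_fun)) {
      sig <- signal_fun(ep)
      est <- sec_estimate(sig$x, time = sig$time, windows = windows,
                          power = sig$power,
                          seed = child_seed(seed %||% 0, s, 7L))
    } else {
      est <- sec_estimate(ep, windows = windows, power = power,
                          seed = child_seed(seed %||% 0, s, 7L))
    }
    if (is.null(diffs)) {
      nc <- nrow(est$corrected$difference)
      nt <- ncol(est$corrected$difference)
      diffs <- array(NA_real_, dim = c(n_sub, nc, nt))
      ttvs <- array(NA_real_, dim = c(n_sub, nc, ncol(est$ttv_post)))
    }
    diffs[s, , ] <- est$corrected$difference
    ttvs[s, , ] <- est$ttv_post
    summaries[[s]] <- est
  }
  list(diff = diffs, ttv = ttvs, estimates = summaries,
       resp_time = summaries[[1]]$resp_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the two-simulation methodological discrepancy experiment
#'
#' Generates two simulated cohorts: (1) a genuine (negative) correlation
#' between spontaneous and evoked time-domain activity, implemented as an
#' additive half-sine response whose amplitude is `gain x prestimulus value`
#' with a negative gain; and (2) an oscillatory power reduction with no
#' additional time-domain response (`desync`). Both cohorts are analyzed
#' with the TTV method and the pseudotrial method on the time-domain signal,
#' with time-only cluster permutation inference. A TTV decrease appears in
#' both; only the genuine-correlation cohort should show a pseudotrial
#' high-vs-low difference.
#'
#' @param overrides named list of [sim_config()] arguments applied to both
#'   cohorts (e.g. smaller `n_subjects` for quick runs).
#' @param n_permutations cluster permutations (default 1000, giving a p
#'   floor of 0.002).
#' @param seed master seed.
#' @return list of class `discrepancy_report`: per cohort
#'   (`coupled`, `desync`) the TTV and pseudotrial [cluster_permutation()]
#'   results plus headline p-values, the config snapshots, and the seed.
#' @export
run_discrepancy <- function(overrides = list(), n_permutations = 1000, seed = 1L) {
  base_args <- utils::modifyList(
    list(seed = child_seed(seed, 1L)), overrides)
  # Coupled arm: evoked amplitude = -1 x prestimulus value (unit-regression
  # quench) over a 300 ms lobe, inside the lag range where spontaneous
  # activity still correlates with its prestimulus mean. The desync arm uses
  # the slower 600 ms lobe of the default config, matching the time scale of
  # oscillatory desynchronization.
  coupled_cfg <- do.call(sim_config, utils::modifyList(
    base_args, list(response_kind = "additive_coupled",
                    response_gain = -abs(base_args$response_gain %||% 1),
                    response_duration =
                      base_args$response_duration %||% 0.3)))
  desync_cfg <- do.call(sim_config, utils::modifyList(
    base_args, list(response_kind = "desync",
                    seed = child_seed(seed, 2L))))
  windows <- window_spec()
  out <- list()
  for (nm in c("coupled", "desync")) {
    cfg <- if (nm == "coupled") coupled_cfg else desync_cfg
    ds <- gen_dataset(cfg)
    grp <- collect_subjects(ds$epochs, windows, power = FALSE,
                            seed = child_seed(seed, 3L))
    pseudo <- cluster_permutation(grp$diff, 0,
                                  n_permutations = n_permutations,
                                  seed = child_seed(seed, 4L, 1L))
    ttv_res <- cluster_permutation(grp$ttv, 0,
                                   n_permutations = n_permutations,
                                   seed = child_seed(seed, 4L, 2L))
    out[[nm]] <- list(
      config = cfg,
      pseudotrial = pseudo,
      ttv = ttv_res,
      p_pseudotrial = min_cluster_p(pseudo),
      p_ttv_decrease = min_cluster_p(ttv_res, sign = "-"),
      resp_time = grp$resp_time,
      mean_difference = apply(grp$diff, c(2, 3), mean),
      mean_ttv = apply(grp$ttv, c(2, 3), mean))
  }
  out$n_permutations <- n_permutations
  out$seed <- seed
  class(out) <- "discrepancy_report"
  out
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("Two-simulation discrepancy experiment\n")
  for (nm in c("coupled", "desync")) {
    cat(sprintf("  %-8s  TTV decrease p = %-8.4g  pseudotrial p = %.4g\n",
                nm, x[[nm]]$p_ttv_decrease, x[[nm]]$p_pseudotrial))
  }
  invisible(x)
}

#' Run the SNR sweep over additive coupled/uncoupled controls
#'
#' For every grid cell from [gen_snr_grid()] and every repetition, generates
#' a cohort, applies both estimators to the time-domain signal, and records
#' whether a significant pseudotrial cluster and a significant TTV decrease
#' were detected.
#'
#' @param grid a [gen_snr_grid()] data.frame.
#' @param reps repetitions per cell (>= 1).
#' @param n_permutations cluster permutations per run.
#' @param alpha cluster-level significance threshold for "detection".
#' @param seed master seed.
#' @return data.frame: one row per (cell, control, rep) with logical columns
#'   `pseudo_detect` and `ttv_decrease` plus the minimum cluster p of each.
#' @export
run_snr_sweep <- function(grid, reps = 1L, n_permutations = 500,
                          alpha = 0.05, seed = 1L) {
  stopifnot(reps >= 1)
  windows <- window_spec()
  rows <- vector("list", nrow(grid) * reps)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(reps)) {
      cfg <- grid$config[[i]]
      cfg$seed <- child_seed(seed, i, r)
      ds <- gen_dataset(cfg)
      grp <- collect_subjects(ds$epochs, windows, power = FALSE,
                              seed = child_seed(seed, i, r, 5L))
      pseudo <- cluster_permutation(grp$diff, 0,
                                    n_permutations = n_permutations,
                                    seed = child_seed(seed, i, r, 6L))
      ttv_res <- cluster_permutation(grp$ttv, 0,
                                     n_permutations = n_permutations,
                                     seed = child_seed(seed, i, r, 7L))
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell = grid$cell[i], snr_base = grid$snr_base[i],
        snr_var = grid$snr_var[i], kind = grid$kind[i], rep = r,
        p_pseudo = min_cluster_p(pseudo),
        p_ttv_decrease = min_cluster_p(ttv_res, sign = "-"))
    }
  }
  out <- do.call(rbind, rows)
  out$pseudo_detect <- out$p_pseudo <= alpha
  out$ttv_decrease <- out$p_ttv_decrease <= alpha
  out
}

#' Full spontaneous-evoked correlation analysis over a cohort
#'
#' Runs the complete chain on a list of per-subject epochs: optional signal
#' extraction (wavelet band power, IRASA oscillatory band power, or a
#' scale-free parameter course), trial/pseudotrial definition, median split,
#' pseudotrial correction and TTV, group-level cluster statistics, effect
#' sizes, per-subject summary indices, and the cross-method Spearman
#' correlation of the two indices.
#'
#' @param epochs_list list of [epochs_set()] (>= 5 subjects).
#' @param signal `"time"`, `"band"` (wavelet band power), `"osc"` (IRASA
#'   oscillatory band power), `"fractal_slope"`, or `"fractal_offset"`.
#' @param band frequency interval, Hz (required for `"band"`/`"osc"`).
#' @param windows a [window_spec()].
#' @param neighbors optional [channel_neighbors()] graph.
#' @param n_permutations cluster permutations.
#' @param alpha cluster significance threshold for the summary-index masks.
#' @param irasa_cfg an [irasa_config()] (IRASA-based signals only).
#' @param n_cycles wavelet cycles (`"band"` only).
#' @param seed master seed.
#' @return list of class `sec_report`: cluster results for both methods,
#'   effect-size maps, per-subject summary indices, the cross-method
#'   Spearman result, and a config snapshot sufficient to re-run.
#' @export
run_sec_analysis <- function(epochs_list,
                             signal = c("time", "band", "osc",
                                        "fractal_slope", "fractal_offset"),
                             band = NULL, windows = window_spec(),
                             neighbors = NULL, n_permutations = 1000,
                             alpha = 0.05, irasa_cfg = irasa_config(),
                             n_cycles = 3, seed = 1L) {
  signal <- match.arg(signal)
  if (length(epochs_list) < 5L) {
    stop_classed("invalid_argument", "need at least 5 subjects")
  }
  if (signal %in% c("band", "osc") && is.null(band)) {
    stop_classed("invalid_argument", "signal '%s' requires a band", signal)
  }
  signal_fun <- switch(signal,
    time = NULL,
    band = function(ep) {
      freqs <- log_freqs()
      freqs <- freqs[freqs >= band[1] & freqs <= band[2]]
      if (!length(freqs)) freqs <- mean(band)
      tfr <- morlet_tfr(ep, freqs = freqs, n_cycles = n_cycles)
      list(x = band_power(tfr, band), time = ep$time, power = TRUE)
    },
    osc = function(ep) {
      need <- seq(min(windows$pseudo_prestim[1], windows$prestim[1]),
                  windows$poststim[2] - irasa_cfg$step / 2,
                  by = irasa_cfg$step)
      sl <- irasa_sliding(ep, irasa_cfg, out_times = need,
                          bands = list(b = band))
      list(x = sl$osc_band[, , 1, , drop = TRUE] |>
             array(dim = dim(sl$osc_band)[c(1, 2, 4)]),
           time = sl$time, power = TRUE)
    },
    fractal_slope = function(ep) {
      need <- seq(min(windows$pseudo_prestim[1], windows$prestim[1]),
                  windows$poststim[2] - irasa_cfg$step / 2,
                  by = irasa_cfg$step)
      sl <- irasa_sliding(ep, irasa_cfg, out_times = need)
      list(x = sl$beta, time = sl$time, power = TRUE)
    },
    fractal_offset = function(ep) {
      need <- seq(min(windows$pseudo_prestim[1], windows$prestim[1]),
                  windows$poststim[2] - irasa_cfg$step / 2,
                  by = irasa_cfg$step)
      sl <- irasa_sliding(ep, irasa_cfg, out_times = need)
      list(x = sl$offset, time = sl$time, power = TRUE)
    })
  grp <- collect_subjects(epochs_list, windows, signal_fun = signal_fun,
                          seed = child_seed(seed, 11L))
  pseudo <- cluster_permutation(grp$diff, 0, neighbors = neighbors,
                                n_permutations = n_permutations,
                                seed = child_seed(seed, 12L))
  ttv_res <- cluster_permutation(grp$ttv, 0, neighbors = neighbors,
                                 n_permutations = n_permutations,
                                 seed = child_seed(seed, 13L))
  dt <- if (length(grp$resp_time) > 1) diff(grp$resp_time[1:2]) else NA
  mask_p <- cluster_mask(pseudo, alpha)
  mask_t <- cluster_mask(ttv_res, alpha)
  n_sub <- length(epochs_list)
  nc <- dim(grp$diff)[2]
  idx_pseudo <- idx_ttv <- matrix(NA_real_, n_sub, nc)
  for (s in seq_len(n_sub)) {
    idx_pseudo[s, ] <- summary_index(
      matrix(grp$diff[s, , ], nc), mask_p, dt)
    idx_ttv[s, ] <- summary_index(
      matrix(grp$ttv[s, , ], nc), mask_t, dt)
  }
  cross <- if (n_sub >= 5 && any(mask_p) && any(mask_t)) {
    spearman_cluster_corr(idx_pseudo, idx_ttv, neighbors = neighbors,
                          n_permutations = n_permutations,
                          seed = child_seed(seed, 14L))
  } else NULL
  structure(list(
    signal = signal, band = band,
    pseudotrial = pseudo, ttv = ttv_res,
    p_pseudotrial = min_cluster_p(pseudo),
    p_ttv_decrease = min_cluster_p(ttv_res, sign = "-"),
    summary_index = list(pseudotrial = idx_pseudo, ttv = idx_ttv),
    cross_method = cross,
    mean_difference = apply(grp$diff, c(2, 3), mean),
    mean_ttv = apply(grp$ttv, c(2, 3), mean),
    resp_time = grp$resp_time,
    config = list(windows = windows, n_permutations = n_permutations,
                  alpha = alpha, n_cycles = n_cycles, seed = seed)),
    class = "sec_report")
}

#' @export
print.sec_report <- function(x, ...) {
  cat(sprintf("sec_report [%s%s]: pseudotrial p = %.4g, TTV decrease p = %.4g\n",
              x$signal,
              if (!is.null(x$band)) sprintf(" %g-%g Hz", x$band[1], x$band[2])
              else "",
              x$p_pseudotrial, x$p_ttv_decrease))
  invisible(x)
}
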