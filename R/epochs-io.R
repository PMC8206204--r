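# Standard-format I/O for epoched data.
#
# Two on-disk formats are supported:
#   * "feather": a documented, versioned Arrow/Feather layout (lossless,
#     language-neutral; readable from Python via pyarrow). One long-format
#     table with columns trial (int32), time (float64), and one float64
#     column per channel; sampling rate, subject id, channel positions and a
#     layout version live in the Arrow schema metadata.
#   * "edf": European Data Format (16-bit, continuous) with an EDF+
#     annotations channel carrying stimulus-onset events. Epochs are
#     concatenated into a continuous record on write and re-cut around the
#     annotated onsets on read. EDF quantizes samples to 16 bits, so round
#     trips are exact only to quantization precision.

EPOCHS_LAYOUT_VERSION <- "1"

#' Write an epochs set to disk
#'
#' @param epochs an [epochs_set()].
#' @param path output file path.
#' @param format `"feather"` (lossless) or `"edf"` (16-bit, continuous with
#'   onset annotations).
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path, format = c("feather", "edf")) {
  stopifnot(inherits(epochs, "epochs_set"))
  format <- match.arg(format)
  if (format == "feather") {
    write_epochs_feather(epochs, path)
  } else {
    write_epochs_edf(epochs, path)
  }
  invisible(path)
}

#' Read an epochs set from disk
#'
#' @param path input file path.
#' @param format `"feather"` or `"edf"`.
#' @param epoch_window for EDF input: the window (seconds, half-open) to cut
#'   around each annotated stimulus onset. Must cover at least
#'   \[-1.0, 0.8\] s.
#' @return an [epochs_set()].
#' @export
read_epochs <- function(path, format = c("feather", "edf"),
                        epoch_window = c(-1, 1)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_classed("format_error", "file not found: %s", path)
  }
  if (format == "feather") {
    read_epochs_feather(path)
  } else {
    read_epochs_edf(path, epoch_window)
  }
}

write_epochs_feather <- function(epochs, path) {
  d <- dim(epochs$data)
  df <- data.frame(
    trial = rep(seq_len(d[1]), each = d[3]),
    time = rep(epochs$time, times = d[1])
  )
  for (c in seq_len(d[2])) {
    df[[epochs$channel_names[c]]] <- as.numeric(t(epochs$data[, c, ]))
  }
  tbl <- arrow::arrow_table(df)
  tbl$metadata$sevcor_layout <- EPOCHS_LAYOUT_VERSION
  tbl$metadata$sampling_rate <- format(epochs$sampling_rate, digits = 17)
  tbl$metadata$subject_id <- epochs$subject_id
  tbl$metadata$channel_names <- jsonlite::toJSON(epochs$channel_names)
  if (!is.null(epochs$channel_positions)) {
    tbl$metadata$channel_positions <-
      jsonlite::toJSON(epochs$channel_positions)
  }
  arrow::write_feather(tbl, path)
}

read_epochs_feather <- function(path) {
  tbl <- tryCatch(arrow::read_feather(path, as_data_frame = FALSE),
                  error = function(e) {
                    stop_classed("format_error",
                                 "not a readable Feather file: %s", path)
                  })
  md <- tbl$metadata
  if (is.null(md$sampling_rate)) {
    stop_classed("format_error",
                 "epochs layout: missing sampling_rate metadata")
  }
  if (is.null(md$sevcor_layout)) {
    stop_classed("format_error", "epochs layout: missing layout version")
  }
  df <- as.data.frame(tbl)
  chan <- setdiff(names(df), c("trial", "time"))
  if (!all(c("trial", "time") %in% names(df)) || length(chan) == 0) {
    stop_classed("format_error",
                 "epochs layout: need trial, time and channel columns")
  }
  trials <- sort(unique(df$trial))
  n_samp <- sum(df$trial == trials[1])
  time <- df$time[df$trial == trials[1]]
  dat <- array(NA_real_, dim = c(length(trials), length(chan), n_samp))
  for (i in seq_along(trials)) {
    sub <- df[df$trial == trials[i], , drop = FALSE]
    for (c in seq_along(chan)) dat[i, c, ] <- sub[[chan[c]]]
  }
  pos <- if (!is.null(md$channel_positions)) {
    matrix(jsonlite::fromJSON(md$channel_positions), ncol = 2)
  } else NULL
  epochs_set(dat, time = time,
             sampling_rate = as.numeric(md$sampling_rate),
             channel_names = unlist(jsonlite::fromJSON(md$channel_names)),
             channel_positions = pos,
             subject_id = if (is.null(md$subject_id)) "S01" else md$subject_id)
}

# ---------------------------------------------------------------------------
# EDF (16-bit European Data Format, continuous, EDF+C with annotations).
# Implemented directly over the published fixed-layout byte format.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_epochs_edf <- function(epochs, path) {
  d <- dim(epochs$data)
  fs <- epochs$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop_classed("format_error", "EDF writer requires an integer sampling rate")
  }
  fs <- as.integer(round(fs))
  n_chan <- d[2]
  # concatenate epochs back-to-back into a continuous signal
  cont <- matrix(0, nrow = n_chan, ncol = d[1] * d[3])
  for (c in seq_len(n_chan)) cont[c, ] <- as.numeric(t(epochs$data[, c, ]))
  onset_sample <- which.min(abs(epochs$time))   # sample where t == 0
  onsets <- ((seq_len(d[1]) - 1L) * d[3] + onset_sample - 1L) / fs
  n_rec <- ceiling(ncol(cont) / fs)
  if (n_rec * fs > ncol(cont)) {                # pad final record with zeros
    cont <- cbind(cont, matrix(0, n_chan, n_rec * fs - ncol(cont)))
  }
  # physical scaling per channel
  pmin_ <- apply(cont, 1, min); pmax_ <- apply(cont, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  ann_len <- 120L                               # bytes per record for TALs
  ns <- n_chan + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X X subject", epochs$subject_id), 80),
    "01.01.01", "00.00.00",
    edf_pad(256 * (1 + ns), 8), edf_pad("EDF+C", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  field <- function(vals, width) {
    paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  }
  labels <- c(substr(epochs$channel_names, 1, 16), "EDF Annotations")
  hdr <- paste0(hdr,
    field(labels, 16),
    field(rep("", ns), 80),
    field(c(rep("au", n_chan), ""), 8),
    field(c(formatC(pmin_, digits = 5, format = "g"), "-1"), 8),
    field(c(formatC(pmax_, digits = 5, format = "g"), "1"), 8),
    field(c(rep("-32768", n_chan), "-32768"), 8),
    field(c(rep("32767", n_chan), "32767"), 8),
    field(rep("", ns), 80),
    field(c(rep(fs, n_chan), ann_len / 2), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(n_chan)) {
      dig <- round((cont[c, idx] - pmin_[c]) / scale[c]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
    t_rec <- r - 1L
    tal <- sprintf("+%d\x14\x14", t_rec)
    in_rec <- onsets[onsets >= t_rec & onsets < t_rec + 1]
    for (o in in_rec) tal <- paste0(tal, sprintf("+%.6f\x14stim\x14", o))
    raw_tal <- c(charToRaw(tal), as.raw(0))
    if (length(raw_tal) > ann_len) {
      stop_classed("format_error", "too many annotations in one EDF record")
    }
    writeBin(c(raw_tal, raw(ann_len - length(raw_tal))), con)
  }
  invisible(path)
}

read_epochs_edf <- function(path, epoch_window = c(-1, 1)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || is.na(n_rec)) {
    stop_classed("format_error", "not a parseable EDF header: %s", path)
  }
  sig_field <- function(width) {
    vapply(seq_len(ns), function(i) rd(width), "")
  }
  labels <- sig_field(16); sig_field(80); sig_field(8)
  pmin_ <- as.numeric(sig_field(8)); pmax_ <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)
  nsamp <- as.integer(sig_field(8)); sig_field(32)
  ann_idx <- which(labels == "EDF Annotations")
  dat_idx <- setdiff(seq_len(ns), ann_idx)
  if (length(ann_idx) == 0) {
    stop_classed("format_error",
                 "EDF file has no annotations channel (no stimulus onsets)")
  }
  fs <- nsamp[dat_idx[1]] / rec_dur
  sig <- lapply(dat_idx, function(i) numeric(n_rec * nsamp[i]))
  names(sig) <- labels[dat_idx]
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_idx) {
        bytes <- readBin(con, "raw", n = nsamp[i] * 2)
        ann_text <- c(ann_text, rawToChar(bytes[bytes != as.raw(0)],
                                          multiple = FALSE))
      } else {
        dig <- readBin(con, "integer", n = nsamp[i], size = 2,
                       endian = "little")
        j <- match(i, dat_idx)
        phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
          (dmax[i] - dmin[i])
        sig[[j]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <- phys
      }
    }
  }
  # parse TALs: events are "+onset\x14text\x14"; record keepers have empty text
  tals <- unlist(strsplit(paste(ann_text, collapse = ""), "\x14\x14",
                          fixed = TRUE))
  onsets <- numeric(0)
  for (chunk in tals) {
    parts <- unlist(strsplit(chunk, "\x14", fixed = TRUE))
    k <- 1L
    while (k < length(parts)) {
      if (grepl("^[+-][0-9.]+$", parts[k]) && nzchar(trimws(parts[k + 1]))) {
        onsets <- c(onsets, as.numeric(parts[k]))
      }
      k <- k + 1L
    }
  }
  if (length(onsets) == 0) {
    stop_classed("format_error", "EDF file contains no event annotations")
  }
  lo <- round(epoch_window[1] * fs); hi <- round(epoch_window[2] * fs)
  n_samp <- hi - lo
  total <- length(sig[[1]])
  keep <- onsets[round(onsets * fs) + lo >= 0 &
                   round(onsets * fs) + hi <= total]
  if (length(keep) < 2) {
    stop_classed("window_error",
                 "fewer than 2 onsets leave room for the epoch window")
  }
  dat <- array(NA_real_, dim = c(length(keep), length(sig), n_samp))
  for (e in seq_along(keep)) {
    s0 <- round(keep[e] * fs) + lo
    for (c in seq_along(sig)) dat[e, c, ] <- sig[[c]][(s0 + 1L):(s0 + n_samp)]
  }
  epochs_set(dat, time = (lo:(hi - 1L)) / fs, sampling_rate = fs,
             channel_names = names(sig), subject_id = "edf")
}
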