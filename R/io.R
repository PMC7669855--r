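# I/O: minimal European Data Format (EDF) reader/writer, epoching of
# continuous recordings, and the on-disk epochs container (lossless CSV
# tensor + JSON sidecar). No R EDF package is assumed; the format's fixed
# 256-byte ASCII headers and 16-bit little-endian records are read
# directly.

#' Write continuous data to an EDF file
#'
#' Minimal single-session EDF writer (one data record per second,
#' per-channel symmetric physical scaling to the 16-bit digital range).
#' Intended for round-trip tests and small exports; amplitude resolution
#' is limited by the 16-bit quantization.
#'
#' @param path output file.
#' @param data channels x samples matrix (microvolts).
#' @param sfreq sampling rate (Hz, integer).
#' @param channels channel names.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, data, sfreq, channels = rownames(data)) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  ns <- nrow(data)
  spr <- as.integer(sfreq)
  n_rec <- ceiling(ncol(data) / spr)
  pad <- n_rec * spr - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, ns, pad))
  pmax_ <- apply(abs(data), 1, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- ceiling(pmax_ * 1.01)
  fixed <- function(x, w) {
    s <- substr(format(x, width = w), 1, w)
    sprintf(paste0("%-", w, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    fixed("0", 8), fixed("synthetic subject", 80),
    fixed("caninevep export", 80),
    fixed("01.01.26", 8), fixed("00.00.00", 8),
    fixed(256 * (1 + ns), 8), fixed("", 44),
    fixed(n_rec, 8), fixed(1, 8), fixed(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, w) {
    writeChar(paste(vapply(vals, fixed, "", w = w), collapse = ""),
              con, eos = NULL)
  }
  field(channels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(-pmax_, 8)
  field(pmax_, 8)
  field(rep(-32768, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  scale <- 65535 / (2 * pmax_)
  for (rec in seq_len(n_rec)) {
    cols <- (rec - 1) * spr + seq_len(spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((data[ch, cols] + pmax_[ch]) * scale[ch])) -
        32768L
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a standard EDF recording into a continuous channels x samples
#' matrix in physical units, and optionally detects stimulus events as
#' upward threshold crossings of a trigger channel.
#'
#' @param path EDF file.
#' @param trigger_channel name of the trigger channel, or `NULL`.
#' @param trigger_threshold crossing threshold in the trigger channel's
#'   physical units (default half its maximum).
#' @param drop_trigger remove the trigger channel from the data matrix
#'   (default `TRUE` when a trigger channel is given).
#' @return list with `data` (channels x samples, physical units),
#'   `sfreq`, `channels`, and `events` (onset sample indices, or `NULL`).
#' @export
read_edf <- function(path, trigger_channel = NULL,
                     trigger_threshold = NULL, drop_trigger = TRUE) {
  if (!file.exists(path)) stopf("cannot read EDF file '%s'", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("'%s' is not a well-formed EDF file", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  channels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8))
  dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1) {
    stopf("mixed per-channel sampling rates are not supported")
  }
  seek(con, header_bytes)
  data <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (rec in seq_len(n_rec)) {
    cols <- (rec - 1) * spr[1] + seq_len(spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      data[ch, cols] <- (dig - dmin_[ch]) * gain[ch] + pmin_[ch]
    }
  }
  rownames(data) <- channels
  events <- NULL
  if (!is.null(trigger_channel)) {
    ti <- match(trigger_channel, channels)
    if (is.na(ti)) stopf("trigger channel '%s' not found", trigger_channel)
    trig <- data[ti, ]
    thr <- trigger_threshold %||% (max(trig) / 2)
    above <- trig > thr
    events <- which(above & !c(FALSE, above[-length(above)]))
    if (drop_trigger) {
      data <- data[-ti, , drop = FALSE]
      channels <- channels[-ti]
    }
  }
  list(data = data, sfreq = spr[1] / rec_dur, channels = channels,
       events = events)
}

#' Cut epochs around stimulus events
#'
#' Extracts fixed-length windows around event onsets from a continuous
#' recording; events whose window extends beyond the recording are skipped
#' with a warning (the count is attached as attribute `"n_skipped"`).
#'
#' @param data channels x samples matrix.
#' @param sfreq sampling rate (Hz).
#' @param events onset sample indices (1-based).
#' @param span epoch span in ms relative to onset (default
#'   `c(-150, 350)`).
#' @param labels per-event category labels (recycled `"S"` if omitted).
#' @param subject subject id.
#' @param channels channel names (default from `data` rownames).
#' @return an [epochs_set()].
#' @export
epoch_continuous <- function(data, sfreq, events, span = c(-150, 350),
                             labels = NULL, subject = "sub01",
                             channels = rownames(data)) {
  offset0 <- round(span[1] * sfreq / 1000)
  n_samp <- floor((span[2] - span[1]) * sfreq / 1000) + 1
  times <- (offset0 + seq_len(n_samp) - 1) * 1000 / sfreq
  labels <- labels %||% rep("S", length(events))
  ok <- events + offset0 >= 1 &
    events + offset0 + n_samp - 1 <= ncol(data)
  if (any(!ok)) {
    warnf("%d event(s) outside the recording were skipped", sum(!ok))
  }
  events_ok <- events[ok]
  if (length(events_ok) == 0) stopf("no events inside the recording")
  out <- array(0, c(length(events_ok), nrow(data), n_samp))
  for (i in seq_along(events_ok)) {
    cols <- events_ok[i] + offset0 + seq_len(n_samp) - 1
    out[i, , ] <- data[, cols]
  }
  ep <- epochs_set(out, times, sfreq,
                   channels %||% paste0("ch", seq_len(nrow(data))),
                   labels[ok], subject)
  attr(ep, "n_skipped") <- sum(!ok)
  ep
}

#' Write / read the on-disk epochs container
#'
#' Two plain-text files readable without this package: `<stem>_data.csv`
#' holds the tensor as a trial-major (trial x channel rows, sample
#' columns) CSV with lossless floating-point formatting, and
#' `<stem>_meta.json` holds the time axis, labels and bookkeeping. The
#' round trip reproduces the epochs exactly.
#'
#' @param epochs an [epochs_set()].
#' @param stem path stem (files `<stem>_data.csv`, `<stem>_meta.json`).
#' @return `write_epochs`: the stem, invisibly; `read_epochs`: an
#'   `epochs_set`.
#' @export
write_epochs <- function(epochs, stem) {
  d <- dim(epochs$data)
  flat <- t(matrix(aperm(epochs$data, c(3, 2, 1)), d[3], d[1] * d[2]))
  # %.17g round-trips doubles exactly; fwrite's 15 digits would not
  txt <- matrix(sprintf("%.17g", flat), nrow(flat), ncol(flat))
  con <- file(paste0(stem, "_data.csv"), "w")
  writeLines(paste(paste0("s", seq_len(d[3])), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  close(con)
  meta <- list(
    container_version = 1L,
    subject = epochs$subject, sfreq = epochs$sfreq,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    channels = epochs$channels, times = epochs$times,
    labels = epochs$labels, kept = epochs$kept,
    reject_reason = epochs$reject_reason,
    artifact = epochs$artifact
  )
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(paste0(stem, "_data.csv")))
  data <- aperm(array(t(flat), c(meta$n_samples, meta$n_channels,
                                 meta$n_trials)), c(3, 2, 1))
  epochs_set(data, meta$times, meta$sfreq, meta$channels, meta$labels,
             meta$subject, meta$kept, meta$reject_reason,
             if (!is.null(meta$artifact)) as.logical(meta$artifact))
}
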