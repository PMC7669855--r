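#' Epoched multi-channel EEG container
#'
#' The substrate of every analysis stage: a trials x channels x samples
#' tensor of epoched EEG (in microvolts) with a millisecond time axis
#' relative to stimulus onset, per-trial category labels, a subject id and
#' per-trial kept/rejected bookkeeping.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param times numeric vector of sample times (ms relative to stimulus
#'   onset); must be strictly increasing and uniformly spaced at `sfreq`.
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel names.
#' @param labels character vector (or factor) of per-trial category labels.
#' @param subject subject identifier.
#' @param kept logical per-trial flag; rejected trials stay in the tensor.
#' @param reject_reason character per-trial reason ("" when kept).
#' @param artifact optional logical vector marking simulated artifact trials
#'   (ground truth from the generator; `NA` for real data).
#' @return an object of class `epochs_set`.
#' @export
epochs_set <- function(data, times, sfreq, channels, labels, subject,
                       kept = NULL, reject_reason = NULL, artifact = NULL) {
  if (length(dim(data)) != 3L) {
    stopf("data: expected a 3-d trials x channels x samples array")
  }
  n_trials <- dim(data)[1]
  n_ch <- dim(data)[2]
  n_samp <- dim(data)[3]
  if (length(channels) != n_ch) {
    stopf("channels: %d names for %d channels", length(channels), n_ch)
  }
  if (length(times) != n_samp) {
    stopf("times: %d time points for %d samples", length(times), n_samp)
  }
  if (length(labels) != n_trials) {
    stopf("labels: %d labels for %d trials", length(labels), n_trials)
  }
  if (!all(is.finite(data))) stopf("data: non-finite values")
  dt <- diff(times)
  if (n_samp > 1) {
    if (any(dt <= 0)) stopf("times: must be strictly increasing")
    if (max(abs(dt - 1000 / sfreq)) > 1e-6) {
      stopf("times: spacing inconsistent with sampling rate %g Hz", sfreq)
    }
  }
  kept <- kept %||% rep(TRUE, n_trials)
  reject_reason <- reject_reason %||% rep("", n_trials)
  structure(
    list(
      data = data,
      times = as.numeric(times),
      sfreq = sfreq,
      channels = as.character(channels),
      labels = as.character(labels),
      subject = as.character(subject),
      kept = as.logical(kept),
      reject_reason = as.character(reject_reason),
      artifact = artifact
    ),
    class = "epochs_set"
  )
}

#' @export
print.epochs_set <- function(x, ...) {
  cat(sprintf(
    "<epochs_set> subject %s: %d trials (%d kept) x %d channels x %d samples\n",
    x$subject, n_trials(x), sum(x$kept), length(x$channels),
    length(x$times)
  ))
  cat(sprintf("  time %g..%g ms @ %g Hz; labels: %s\n",
              min(x$times), max(x$times), x$sfreq,
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Number of trials in an epochs set
#' @param x an `epochs_set`.
#' @return integer trial count (kept + rejected).
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Subset trials of an epochs set
#' @param x an `epochs_set`.
#' @param i trial indices or a logical mask.
#' @return a new `epochs_set` with the selected trials.
#' @export
subset_trials <- function(x, i) {
  epochs_set(x$data[i, , , drop = FALSE], x$times, x$sfreq, x$channels,
             x$labels[i], x$subject, x$kept[i], x$reject_reason[i],
             if (!is.null(x$artifact)) x$artifact[i])
}

# Binned epochs keep the epochs_set fields but carry a bin table instead of
# a uniform sample axis; most epochs_set verbs do not apply to them.
binned_epochs <- function(data, bin_start, bin_end, channels, labels,
                          subject, kept, reject_reason = NULL) {
  structure(
    list(
      data = data,
      bin_start = bin_start,
      bin_end = bin_end,
      times = (bin_start + bin_end) / 2,
      channels = as.character(channels),
      labels = as.character(labels),
      subject = as.character(subject),
      kept = as.logical(kept),
      reject_reason = reject_reason %||% rep("", dim(data)[1])
    ),
    class = c("binned_epochs")
  )
}

#' @export
print.binned_epochs <- function(x, ...) {
  cat(sprintf(
    "<binned_epochs> subject %s: %d trials x %d channels x %d bins (%g ms)\n",
    x$subject, dim(x$data)[1], length(x$channels), length(x$bin_start),
    x$bin_end[1] - x$bin_start[1]
  ))
  invisible(x)
}

#' Single-trial feature matrix for decoding
#'
#' Rows are trials, columns are bin-averaged channel amplitudes; column
#' metadata records the (channel, bin) behind every feature so the matrix
#' can be mapped back onto the sensor x time grid.
#'
#' @param x numeric matrix, trials x features.
#' @param labels per-trial category labels.
#' @param channel,bin_start,bin_end per-column metadata vectors.
#' @param subject subject identifier.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, channel, bin_start, bin_end,
                           subject = "") {
  if (nrow(x) != length(labels)) stopf("labels: one per row required")
  if (ncol(x) != length(channel) || ncol(x) != length(bin_start) ||
      ncol(x) != length(bin_end)) {
    stopf("column metadata must cover every column exactly once")
  }
  structure(
    list(x = x, labels = as.character(labels),
         channel = as.character(channel),
         bin_start = bin_start, bin_end = bin_end,
         subject = as.character(subject)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%d channels)\n",
              nrow(x$x), ncol(x$x), length(unique(x$channel))))
  invisible(x)
}
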