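# Preprocessing: the two analysis streams.
#
# ERP stream:      2-40 Hz band-pass, 100 uV rejection, baseline correction.
# Decoding stream: 2-25 Hz band-pass, 20-ms binning, vectorization; all
#                  trials are kept for decoding, rejection only flags.

# Apply a function over every trial x channel trace of the tensor.
map_traces <- function(data, f) {
  d <- dim(data)
  flat <- matrix(aperm(data, c(3, 1, 2)), d[3], d[1] * d[2])
  flat <- f(flat)
  aperm(array(flat, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Zero-phase band-pass filter
#'
#' Cascade of 4th-order Butterworth high-pass and low-pass filters, each
#' applied forward-backward (zero phase) with reflective padding of at
#' least three time constants of the high-pass corner, so a symmetric
#' pulse keeps its peak latency and edge transients do not reach the epoch
#' interior. The cascade (rather than a single band-pass design) keeps the
#' recursion numerically stable for narrow low-frequency bands at EEG
#' sampling rates.
#'
#' @param epochs an [epochs_set()].
#' @param low,high band edges in Hz; `0 < low < high < ` Nyquist.
#' @param order filter order of each cascade stage (default 4).
#' @return a filtered `epochs_set` of the same shape.
#' @export
bandpass_filter <- function(epochs, low, high, order = 4) {
  nyq <- epochs$sfreq / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("band [%g, %g] Hz outside (0, %g) Hz Nyquist range", low, high, nyq)
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  n <- length(epochs$times)
  pad <- min(n - 1, ceiling(3 * epochs$sfreq / low))
  epochs$data <- map_traces(epochs$data, function(flat) {
    apply(flat, 2, function(x) {
      # even (mirror) reflection: no spurious step in the local mean at
      # the junctions, which the low high-pass corner would smear inward
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
      y <- signal::filtfilt(lp, signal::filtfilt(hp, xp))
      y[(pad + 1):(pad + n)]
    })
  })
  epochs
}

#' Remove stimulus-trigger leak by linear regression
#'
#' Per trial and channel, fits amplitude and intercept of a known per-sample
#' leak regressor by least squares and subtracts the fit; the residual is
#' orthogonal to the regressor.
#'
#' @param epochs an [epochs_set()].
#' @param regressor numeric vector of the leak waveform, one value per
#'   sample (see [trigger_leak_template()]).
#' @return a cleaned `epochs_set`.
#' @export
remove_trigger_leak <- function(epochs, regressor) {
  n <- length(epochs$times)
  if (length(regressor) != n) {
    stopf("regressor: length %d != %d samples per epoch",
          length(regressor), n)
  }
  if (all(regressor == 0)) {
    warnf("regressor is all zero; returning data unchanged")
    return(epochs)
  }
  X <- cbind(1, regressor)
  H <- X %*% solve(crossprod(X), t(X))
  epochs$data <- map_traces(epochs$data, function(flat) flat - H %*% flat)
  epochs
}

#' Flag trials with excessive amplitude deviations
#'
#' A trial is rejected when, on any channel, the absolute deviation from
#' that trial's own mean within the inspection window exceeds `threshold`.
#' Rejected trials remain in the tensor with `kept = FALSE`; kept trials
#' are unmodified. The per-trial report is attached as attribute
#' `"rejection_report"`.
#'
#' @param epochs an [epochs_set()].
#' @param threshold rejection threshold in microvolts (100 for the ERP
#'   stream, 50 for the source-modelling stream).
#' @param window inspection window in ms, default \[-150, 350\].
#' @return the `epochs_set` with updated kept/rejected flags.
#' @export
reject_by_amplitude <- function(epochs, threshold = 100,
                                window = c(-150, 350)) {
  if (threshold <= 0) stopf("threshold: must be > 0")
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stopf("window [%g, %g] ms contains no samples",
                       window[1], window[2])
  if (window[1] < min(epochs$times) - 1e-9 ||
      window[2] > max(epochs$times) + 1000 / epochs$sfreq) {
    stopf("window [%g, %g] ms not contained in the epoch span",
          window[1], window[2])
  }
  seg <- epochs$data[, , sel, drop = FALSE]
  mu <- apply(seg, c(1, 2), mean)
  dev <- apply(abs(sweep(seg, c(1, 2), mu, "-")), c(1, 2), max)
  max_dev <- apply(dev, 1, max)
  worst_ch <- epochs$channels[apply(dev, 1, which.max)]
  bad <- max_dev > threshold
  epochs$kept <- epochs$kept & !bad
  epochs$reject_reason[bad] <- "amplitude"
  attr(epochs, "rejection_report") <- data.frame(
    trial = seq_len(n_trials(epochs)),
    channel = worst_ch,
    max_deviation = max_dev,
    decision = ifelse(bad, "reject", "keep")
  )
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window; applying it twice equals applying it once.
#'
#' @param epochs an [epochs_set()].
#' @param window baseline window in ms, default \[-150, 0\].
#' @return a baseline-corrected `epochs_set`.
#' @export
baseline_correct <- function(epochs, window = c(-150, 0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stopf("baseline window [%g, %g] ms contains no samples",
                       window[1], window[2])
  mu <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- sweep(epochs$data, c(1, 2), mu, "-")
  epochs
}

#' Average epochs into non-overlapping time bins
#'
#' Bins are half-open intervals `[t0 + k*w, t0 + (k+1)*w)` ms on the time
#' axis (not fixed sample counts: 20 ms at 512 Hz alternates between 10 and
#' 11 samples per bin); every output value is the mean of the input samples
#' whose timestamps fall in the bin, and a trailing bin extending past the
#' sampled coverage is dropped.
#'
#' @param epochs an [epochs_set()].
#' @param bin_width bin width in ms (default 20).
#' @return a `binned_epochs` object.
#' @export
bin_epochs <- function(epochs, bin_width = 20) {
  dt <- 1000 / epochs$sfreq
  if (bin_width < dt) {
    stopf("bin_width %g ms is below the %g ms sample period", bin_width, dt)
  }
  t0 <- epochs$times[1]
  coverage_end <- epochs$times[length(epochs$times)] + dt
  idx <- floor((epochs$times - t0) / bin_width)
  n_bins <- 0
  while (t0 + (n_bins + 1) * bin_width <= coverage_end + 1e-9) {
    n_bins <- n_bins + 1
  }
  if (n_bins < 1) stopf("epoch shorter than one bin")
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[2], n_bins))
  for (k in seq_len(n_bins)) {
    sel <- idx == (k - 1)
    out[, , k] <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  binned_epochs(out,
                bin_start = t0 + (seq_len(n_bins) - 1) * bin_width,
                bin_end = t0 + seq_len(n_bins) * bin_width,
                channels = epochs$channels, labels = epochs$labels,
                subject = epochs$subject, kept = epochs$kept,
                reject_reason = epochs$reject_reason)
}

#' Vectorize binned epochs into a feature matrix
#'
#' Whole-epoch mode concatenates all bins of all channels (channel-major:
#' all bins of channel 1, then channel 2, ...) into one row per trial;
#' single-interval mode keeps one bin, giving one feature per channel.
#' For the 7-channel montage with 43 bins of 20 ms this yields
#' 301-dimensional (whole-epoch) and 7-dimensional (single-interval)
#' vectors.
#'
#' @param binned a `binned_epochs` object from [bin_epochs()].
#' @param mode `"whole"` or `"interval"`.
#' @param interval bin index (required iff `mode = "interval"`).
#' @return a [feature_matrix()].
#' @export
vectorize_features <- function(binned, mode = c("whole", "interval"),
                               interval = NULL) {
  mode <- match.arg(mode)
  d <- dim(binned$data)
  n_bins <- d[3]
  if (mode == "interval") {
    if (is.null(interval)) stopf("interval: required in single-interval mode")
    if (interval < 1 || interval > n_bins) {
      stopf("interval %d out of range 1..%d", interval, n_bins)
    }
    x <- binned$data[, , interval, drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[1])
    colnames(x) <- binned$channels
    return(feature_matrix(x, binned$labels, binned$channels,
                          rep(binned$bin_start[interval], d[2]),
                          rep(binned$bin_end[interval], d[2]),
                          subject = binned$subject))
  }
  if (!is.null(interval)) stopf("interval: only valid in single-interval mode")
  # channel-major: channel varies slowest, bin fastest
  x <- matrix(0, d[1], d[2] * n_bins)
  channel <- character(d[2] * n_bins)
  bin_start <- numeric(d[2] * n_bins)
  bin_end <- numeric(d[2] * n_bins)
  for (c_i in seq_len(d[2])) {
    cols <- (c_i - 1) * n_bins + seq_len(n_bins)
    x[, cols] <- binned$data[, c_i, ]
    channel[cols] <- binned$channels[c_i]
    bin_start[cols] <- binned$bin_start
    bin_end[cols] <- binned$bin_end
  }
  feature_matrix(x, binned$labels, channel, bin_start, bin_end,
                 subject = binned$subject)
}
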