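# Preprocessing: filtering, trigger-leak regression, amplitude rejection,
# baseline correction, binning and vectorization.

interior <- function(times, margin = 100) {
  times > min(times) + margin & times < max(times) - margin
}

test_that("band-pass filter removes DC and keeps passband amplitude", {
  n <- 512
  ep <- tiny_epochs(array(7, c(1, 1, n)))
  out <- bandpass_filter(ep, 2, 40)
  expect_lt(max(abs(out$data[1, 1, interior(out$times)])), 0.05)

  t_s <- (seq_len(n) - 1) / 512
  ep10 <- tiny_epochs(array(sin(2 * pi * 10 * t_s), c(1, 1, n)))
  out10 <- bandpass_filter(ep10, 2, 40)
  sel <- interior(ep10$times)
  expect_gt(max(abs(out10$data[1, 1, sel])), 0.95)
  expect_lt(max(abs(out10$data[1, 1, sel])), 1.05)
})

test_that("band-pass filter attenuates the stopband by at least 20 dB", {
  n <- 512
  t_s <- (seq_len(n) - 1) / 512
  ep <- tiny_epochs(array(sin(2 * pi * 100 * t_s), c(1, 1, n)))
  out <- bandpass_filter(ep, 2, 25)
  expect_lt(max(abs(out$data[1, 1, interior(out$times)])), 10^(-20 / 20))
})

test_that("filtering is zero-phase for a symmetric pulse", {
  n <- 512
  x <- exp(-0.5 * ((seq_len(n) - 256) / 10)^2)
  ep <- tiny_epochs(array(x, c(1, 1, n)))
  out <- bandpass_filter(ep, 2, 40)
  expect_equal(which.max(out$data[1, 1, ]), 256, tolerance = 1)
})

test_that("out-of-range bands are rejected", {
  ep <- noise_epochs(2, 1, 128)
  expect_error(bandpass_filter(ep, 0, 40), "band")
  expect_error(bandpass_filter(ep, 2, 300), "band")
  expect_error(bandpass_filter(ep, 30, 10), "band")
})

test_that("trigger-leak regression removes the leak and keeps the signal", {
  n <- 256
  times <- -150 + (seq_len(n) - 1) * 1000 / 512
  reg <- trigger_leak_template(times)
  # pure leak
  ep <- tiny_epochs(array(rep(3 * reg, each = 1), c(1, 1, n)))
  out <- remove_trigger_leak(ep, reg)
  expect_lt(max(abs(out$data)), 1e-10)
  # leak + signal orthogonal to {intercept, regressor}: normal-equations
  # oracle says the signal passes through untouched
  sig <- sin(2 * pi * 8 * (seq_len(n) - 1) / 512)
  X <- cbind(1, reg)
  sig <- sig - as.numeric(X %*% solve(crossprod(X), crossprod(X, sig)))
  ep2 <- tiny_epochs(array(sig + 2.5 * reg, c(1, 1, n)))
  out2 <- remove_trigger_leak(ep2, reg)
  expect_lt(max(abs(out2$data[1, 1, ] - sig)), 1e-6)
  # residual orthogonal to the regressor for random inputs
  ep3 <- noise_epochs(4, 2, n, seed = 7)
  out3 <- remove_trigger_leak(ep3, reg)
  for (i in 1:4) for (ch in 1:2) {
    expect_lt(abs(sum(out3$data[i, ch, ] * reg)), 1e-8)
  }
  expect_warning(remove_trigger_leak(ep3, rep(0, n)), "zero")
})

test_that("amplitude rejection flags only spikes inside the window", {
  n <- 308  # -250..350 ms at 512 Hz
  ep <- tiny_epochs(array(0, c(3, 2, n)), t0 = -250)
  out <- reject_by_amplitude(ep, 100, c(-150, 350))
  expect_equal(sum(!out$kept), 0)

  spike_at <- function(t_ms) {
    d <- array(0, c(3, 2, n))
    d[2, 1, which.min(abs(ep$times - t_ms))] <- 150
    tiny_epochs(d, t0 = -250)
  }
  out2 <- reject_by_amplitude(spike_at(100), 100, c(-150, 350))
  expect_equal(which(!out2$kept), 2L)
  expect_equal(out2$reject_reason[2], "amplitude")
  rep2 <- attr(out2, "rejection_report")
  expect_equal(rep2$decision, c("keep", "reject", "keep"))

  out3 <- reject_by_amplitude(spike_at(-200), 100, c(-150, 350))
  expect_equal(sum(!out3$kept), 0)

  expect_error(reject_by_amplitude(ep, -5), "threshold")
  expect_error(reject_by_amplitude(ep, 100, c(500, 600)), "window")
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  n <- 256
  ep <- tiny_epochs(array(5, c(1, 1, n)))
  out <- baseline_correct(ep)
  expect_equal(max(abs(out$data)), 0)

  d <- array(0, c(1, 1, n))
  ep2 <- tiny_epochs(d)
  ep2$data[1, 1, ep2$times <= 0] <- 5
  ep2$data[1, 1, ep2$times > 0] <- 12
  out2 <- baseline_correct(ep2)
  expect_equal(unique(round(out2$data[1, 1, ep2$times > 0], 10)), 7)
  expect_equal(unique(round(out2$data[1, 1, ep2$times <= 0], 10)), 0)

  ep3 <- noise_epochs(3, 2, n, seed = 5)
  once <- baseline_correct(ep3)
  twice <- baseline_correct(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep3, c(900, 1000)), "window")
})

test_that("binning tiles the epoch and drops a trailing partial bin", {
  # 441 samples at 512 Hz starting at -150 ms cover 861.3 ms -> 43 bins
  ep <- noise_epochs(2, 7, 441, seed = 3)
  b <- bin_epochs(ep, 20)
  expect_equal(length(b$bin_start), 43)
  expect_equal(b$bin_start[1], -150)
  expect_equal(b$bin_end[43], -150 + 43 * 20)

  # constant signal -> every bin equals it
  epc <- tiny_epochs(array(4, c(1, 1, 441)))
  expect_equal(unique(round(as.vector(bin_epochs(epc, 20)$data), 10)), 4)

  # index-set oracle on random data
  idx <- floor((ep$times - ep$times[1]) / 20)
  for (k in c(1, 7, 43)) {
    sel <- idx == (k - 1)
    expect_equal(b$data[1, 3, k], mean(ep$data[1, 3, sel]),
                 tolerance = 1e-12)
  }
  expect_error(bin_epochs(ep, 0.5), "bin_width")
})

test_that("vectorization yields the documented dimensions", {
  ep <- noise_epochs(4, 7, 441, seed = 9)
  b <- bin_epochs(ep, 20)
  whole <- vectorize_features(b, "whole")
  expect_equal(ncol(whole$x), 301)
  expect_equal(nrow(whole$x), 4)
  single <- vectorize_features(b, "interval", 5)
  expect_equal(ncol(single$x), 7)
  expect_error(vectorize_features(b, "interval", 99), "out of range")
  expect_error(vectorize_features(b, "interval"), "interval")

  ep1 <- noise_epochs(2, 1, 11, seed = 2)
  b1 <- bin_epochs(ep1, 20)
  v1 <- vectorize_features(b1, "whole")
  expect_equal(ncol(v1$x), 1)
  expect_equal(v1$x[1, 1], mean(ep1$data[1, 1, ]), tolerance = 1e-12)
})

test_that("vectorization round-trips through its column metadata", {
  ep <- tiny_epochs(array(seq_len(3 * 2 * 64), c(3, 2, 64)))
  b <- bin_epochs(ep, 20)
  fm <- vectorize_features(b, "whole")
  # rebuild the binned tensor from the metadata
  rebuilt <- array(NA_real_, dim(b$data))
  for (j in seq_len(ncol(fm$x))) {
    ch <- match(fm$channel[j], b$channels)
    bin <- match(fm$bin_start[j], b$bin_start)
    rebuilt[, ch, bin] <- fm$x[, j]
  }
  expect_equal(rebuilt, b$data)
})

test_that("preprocessing is label-blind and preserves trial bookkeeping", {
  ep <- noise_epochs(10, 2, 256, seed = 13,
                     labels = rep(c("S", "OB"), 5))
  perm <- sample(10)
  ep_perm <- subset_trials(ep, perm)
  f1 <- bin_epochs(bandpass_filter(ep, 2, 25), 20)
  f2 <- bin_epochs(bandpass_filter(ep_perm, 2, 25), 20)
  expect_equal(f2$data, f1$data[perm, , , drop = FALSE], tolerance = 1e-12)
  expect_equal(f2$labels, f1$labels[perm])
  # filtering/baseline never change trial count or labels
  expect_equal(n_trials(bandpass_filter(ep, 2, 40)), 10)
  expect_equal(baseline_correct(ep)$labels, ep$labels)
})
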