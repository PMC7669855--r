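# Shared fixture builders: everything is generated in code at test time.

# Minimal epochs with explicit data; labels default to scrambled.
tiny_epochs <- function(data, sfreq = 512, t0 = -150,
                        labels = NULL, channels = NULL,
                        subject = "sub01") {
  d <- dim(data)
  times <- t0 + (seq_len(d[3]) - 1) * 1000 / sfreq
  epochs_set(data, times, sfreq,
             channels %||% paste0("ch", seq_len(d[2])),
             labels %||% rep("S", d[1]), subject)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Epochs of pure Gaussian white noise.
noise_epochs <- function(n_trials, n_channels = 2, n_samples = 256,
                         sd = 1, labels = NULL, seed = 1, sfreq = 512) {
  set.seed(seed)
  tiny_epochs(array(rnorm(n_trials * n_channels * n_samples, sd = sd),
                    c(n_trials, n_channels, n_samples)),
              sfreq = sfreq, labels = labels)
}

# Two-class feature data with a mean shift on the first feature.
two_class_features <- function(n_per_class, n_features = 7, shift = 0,
                               sd = 1, seed = 1,
                               classes = c("A", "S")) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_features, sd = sd), n, n_features)
  labels <- rep(classes, each = n_per_class)
  x[labels == classes[1], 1] <- x[labels == classes[1], 1] + shift
  list(x = x, labels = labels)
}

# Per-subject evoked lists for the six face conditions: a common noise
# background plus optional condition offsets added on one channel within a
# latency window.
face_evokeds <- function(n_subjects = 8, n_channels = 2, sfreq = 512,
                         t_range = c(-150, 350), noise_sd = 0.5,
                         effect = NULL, seed = 1) {
  times <- seq(t_range[1], t_range[2], by = 1000 / sfreq)
  lapply(seq_len(n_subjects), function(s) {
    evs <- lapply(face_categories(), function(cond) {
      set.seed(seed * 10000 + s * 100 + match(cond, face_categories()))
      m <- matrix(rnorm(n_channels * length(times), sd = noise_sd),
                  n_channels, length(times))
      if (!is.null(effect) && cond %in% effect$conditions) {
        sel <- times >= effect$window[1] & times <= effect$window[2]
        m[effect$channel, sel] <- m[effect$channel, sel] + effect$amplitude
      }
      structure(list(data = m, times = times, sfreq = sfreq,
                     channels = paste0("ch", seq_len(n_channels)),
                     condition = cond, subject = sprintf("sub%02d", s),
                     n_trials = 1),
                class = "evoked")
    })
    names(evs) <- face_categories()
    evs
  })
}

# Hand-built decoding_timecourse, for thresholding/aggregation tests.
fake_timecourse <- function(observed, null, tasks, subject = "sub01",
                            interval_start = NULL) {
  structure(
    list(observed = observed, null = null, tasks = tasks,
         intervals = seq_len(ncol(observed)),
         interval_start = interval_start %||%
           (20 * (seq_len(ncol(observed)) - 1)),
         subject = subject, folds = 5, n_perm = dim(null)[1], seed = 1),
    class = "decoding_timecourse"
  )
}
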