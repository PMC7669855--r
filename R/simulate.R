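# Synthetic multi-subject evoked-EEG generator.
#
# Each stimulus category has a deterministic evoked template built from
# Gaussian-shaped components; single trials superpose the template with
# 1/f^alpha background noise, optional white noise, occasional
# high-amplitude artifact transients and an optional stimulus-trigger leak.

#' Specify one evoked component
#'
#' A component is a Gaussian bump in time with a fixed spatial pattern: it
#' peaks at `latency_ms`, has temporal standard deviation `width_ms`, and
#' contributes `amplitude[ch]` microvolts at its peak on each channel, for
#' every trial of the categories it applies to.
#'
#' @param latency_ms peak latency (ms relative to stimulus onset).
#' @param width_ms temporal Gaussian standard deviation (ms), > 0.
#' @param amplitude numeric vector of per-channel peak amplitudes
#'   (microvolts); length must equal the channel count of the simulation.
#' @param categories character vector of category codes the component
#'   applies to.
#' @param name optional component name.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(latency_ms, width_ms, amplitude, categories,
                           name = "component") {
  if (!is.numeric(width_ms) || width_ms <= 0) {
    stopf("width_ms: must be > 0 (component '%s')", name)
  }
  check_categories(categories)
  structure(
    list(latency_ms = latency_ms, width_ms = width_ms,
         amplitude = as.numeric(amplitude),
         categories = as.character(categories), name = name),
    class = "component_spec"
  )
}

# Default component set for the 7-channel canine montage
# (F3, F4, T3, T4, Cz, P3, P4). Latencies follow the response structure
# seen in canine visual ERPs: a dominant posterior response near 105 ms,
# a face-sensitive response near 140 ms, an early threat-related response
# at 30-40 ms, a dog-face (species) difference within 45-100 ms, an
# expression-dependent response near 150 ms and a later social response
# near 260 ms. Amplitudes are in microvolts.
default_components <- function() {
  list(
    component_spec(105, 12, c(1.5, 1.5, 0.8, 0.8, 1.0, 3.0, 3.0),
                   c("AD", "ND", "HD", "AH", "NH", "HH", "OB"),
                   name = "vep105"),
    component_spec(105, 12, 0.5 * c(1.5, 1.5, 0.8, 0.8, 1.0, 3.0, 3.0),
                   "S", name = "vep105_scrambled"),
    component_spec(140, 15, c(0.8, 0.8, 0.6, 0.6, 0.5, 1.5, 1.5),
                   face_categories(), name = "face140"),
    component_spec(35, 8, c(1.2, 1.2, 0.5, 0.5, 0.8, 0.6, 0.6),
                   "AD", name = "threat35"),
    component_spec(75, 15, c(0.3, 0.3, 0.8, 0.8, 0.2, 0.8, 0.8),
                   c("AD", "ND", "HD"), name = "species75"),
    component_spec(150, 12, c(0.4, 0.4, 0.5, 0.3, 0.3, 0.6, 0.6),
                   c("HD", "HH"), name = "happy150"),
    component_spec(260, 20, c(0.5, 0.5, 0.4, 0.4, 0.4, 1.0, 1.0),
                   face_categories(), name = "social260")
  )
}

#' Simulation configuration
#'
#' Describes one simulated experiment: the recording setup (8 subjects,
#' 7 channels, 512 Hz, epochs from -150 to 710 ms), per-category trial
#' counts drawn uniformly from `trials_range`, the evoked component set,
#' and the noise/artifact model.
#'
#' @param n_subjects number of subjects.
#' @param trials_range integer length-2 range; each subject x category cell
#'   draws its trial count uniformly from this range.
#' @param sfreq sampling rate (Hz).
#' @param epoch_span numeric length-2, epoch limits in ms relative to
#'   stimulus onset; must contain \[-150, 350\] ms.
#' @param channels channel names.
#' @param components list of [component_spec()] objects; every amplitude
#'   vector must match `channels` in length.
#' @param noise_sd standard deviation (microvolts) of the 1/f^alpha
#'   background noise per channel and trial.
#' @param noise_exponent spectral exponent alpha of the background noise.
#' @param white_sd standard deviation (microvolts) of additional
#'   independent white noise.
#' @param artifact_prob per-trial probability of a high-amplitude artifact.
#' @param artifact_amplitude artifact size (microvolts); artifact trials
#'   exceed this amplitude at one or more samples.
#' @param leak_amplitude amplitude (microvolts) of the stimulus-trigger
#'   leak added identically to all channels (0 disables it).
#' @param seed master seed; fixed seed gives bit-reproducible output.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, trials_range = c(20, 24))
#' eps <- simulate_experiment(cfg)
#' eps[[1]]
sim_config <- function(n_subjects = 8,
                       trials_range = c(128, 155),
                       sfreq = 512,
                       epoch_span = c(-150, 710),
                       channels = c("F3", "F4", "T3", "T4", "Cz", "P3", "P4"),
                       components = NULL,
                       noise_sd = 4,
                       noise_exponent = 1,
                       white_sd = 2,
                       artifact_prob = 0.06,
                       artifact_amplitude = 150,
                       leak_amplitude = 0,
                       seed = 1L) {
  if (is.null(components)) {
    components <- if (length(channels) == 7) default_components() else
      stopf("components: must be supplied for a %d-channel montage",
            length(channels))
  }
  cfg <- structure(
    list(n_subjects = n_subjects, trials_range = trials_range,
         sfreq = sfreq, epoch_span = epoch_span, channels = channels,
         components = components, noise_sd = noise_sd,
         noise_exponent = noise_exponent, white_sd = white_sd,
         artifact_prob = artifact_prob,
         artifact_amplitude = artifact_amplitude,
         leak_amplitude = leak_amplitude, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1) {
    stopf("n_subjects: must be >= 1")
  }
  if (length(cfg$trials_range) != 2 || any(cfg$trials_range < 1) ||
      cfg$trials_range[1] > cfg$trials_range[2]) {
    stopf("trials_range: must be an increasing range with minimum >= 1")
  }
  if (!is.numeric(cfg$sfreq) || cfg$sfreq <= 0) stopf("sfreq: must be > 0")
  if (length(cfg$epoch_span) != 2 || cfg$epoch_span[1] > -150 ||
      cfg$epoch_span[2] < 350) {
    stopf("epoch_span: must contain [-150, 350] ms")
  }
  if (cfg$noise_sd < 0) stopf("noise_sd: must be >= 0")
  if (cfg$white_sd < 0) stopf("white_sd: must be >= 0")
  if (cfg$artifact_prob < 0 || cfg$artifact_prob > 1) {
    stopf("artifact_prob: must be in [0, 1]")
  }
  if (cfg$artifact_amplitude <= 0) stopf("artifact_amplitude: must be > 0")
  tmin <- cfg$epoch_span[1]
  tmax <- cfg$epoch_span[2]
  for (comp in cfg$components) {
    if (!inherits(comp, "component_spec")) {
      stopf("components: every element must be a component_spec")
    }
    if (length(comp$amplitude) != length(cfg$channels)) {
      stopf("components: amplitude length %d != %d channels (component '%s')",
            length(comp$amplitude), length(cfg$channels), comp$name)
    }
    if (comp$latency_ms < tmin || comp$latency_ms > tmax) {
      stopf("components: latency %g ms outside epoch span (component '%s')",
            comp$latency_ms, comp$name)
    }
  }
  invisible(cfg)
}

sim_times <- function(cfg) {
  dt <- 1000 / cfg$sfreq
  n <- floor((cfg$epoch_span[2] - cfg$epoch_span[1]) / dt) + 1
  cfg$epoch_span[1] + (seq_len(n) - 1) * dt
}

#' Evoked template for one category
#'
#' Sum of all applicable components evaluated on the epoch time axis.
#'
#' @param cfg a [sim_config()].
#' @param category one category code.
#' @return channels x samples matrix (microvolts).
#' @export
category_template <- function(cfg, category) {
  check_categories(category)
  times <- sim_times(cfg)
  out <- matrix(0, length(cfg$channels), length(times))
  for (comp in cfg$components) {
    if (!(category %in% comp$categories)) next
    shape <- exp(-0.5 * ((times - comp$latency_ms) / comp$width_ms)^2)
    out <- out + outer(comp$amplitude, shape)
  }
  out
}

#' Stimulus-trigger leak waveform
#'
#' Exponentially decaying transient starting at stimulus onset, the same on
#' every channel; used both by the generator (when `leak_amplitude > 0`)
#' and as the regressor for [remove_trigger_leak()].
#'
#' @param times time axis in ms.
#' @param tau_ms decay time constant (ms).
#' @return numeric vector of unit peak amplitude, one value per time point.
#' @export
trigger_leak_template <- function(times, tau_ms = 30) {
  ifelse(times >= 0, exp(-times / tau_ms), 0)
}

# 1/f^alpha noise: shape white Gaussian columns in the frequency domain.
# `n_cols` traces of length `n` are generated at unit variance each
# (empirically normalised per trace).
colored_noise <- function(n, n_cols, sfreq, exponent) {
  z <- matrix(stats::rnorm(n * n_cols), n, n_cols)
  if (exponent == 0) return(z)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)           # two-sided frequency index
  scale <- c(0, (f[-1])^(-exponent / 2))
  zf <- stats::mvfft(z) * scale
  x <- Re(stats::mvfft(zf, inverse = TRUE)) / n
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

simulate_subject <- function(cfg, subject_index) {
  times <- sim_times(cfg)
  n_samp <- length(times)
  n_ch <- length(cfg$channels)
  with_seed(derive_seed(cfg$seed, 101, subject_index), {
    counts <- cfg$trials_range[1]:cfg$trials_range[2]
    n_per_cat <- counts[sample.int(length(counts), length(categories()),
                                   replace = TRUE)]
    names(n_per_cat) <- categories()
    n_tot <- sum(n_per_cat)
    labels <- rep(categories(), times = n_per_cat)
    data <- array(0, c(n_tot, n_ch, n_samp))
    templates <- lapply(categories(), function(cat) category_template(cfg, cat))
    names(templates) <- categories()
    for (cat in categories()) {
      idx <- which(labels == cat)
      tmpl <- templates[[cat]]
      for (i in idx) data[i, , ] <- tmpl
    }
    if (cfg$noise_sd > 0) {
      nz <- colored_noise(n_samp, n_tot * n_ch, cfg$sfreq, cfg$noise_exponent)
      data <- data + cfg$noise_sd *
        aperm(array(nz, c(n_samp, n_tot, n_ch)), c(2, 3, 1))
    }
    if (cfg$white_sd > 0) {
      data <- data + array(stats::rnorm(n_tot * n_ch * n_samp,
                                        sd = cfg$white_sd),
                           c(n_tot, n_ch, n_samp))
    }
    if (cfg$leak_amplitude != 0) {
      leak <- cfg$leak_amplitude * trigger_leak_template(times)
      data <- data + aperm(array(leak, c(n_samp, n_tot, n_ch)), c(2, 3, 1))
    }
    artifact <- stats::runif(n_tot) < cfg$artifact_prob
    if (any(artifact)) {
      for (i in which(artifact)) {
        ch <- sample.int(n_ch, 1)
        center <- stats::runif(1, times[1] + 20, times[n_samp] - 20)
        sign_a <- sample(c(-1, 1), 1)
        bump <- sign_a * 1.5 * cfg$artifact_amplitude *
          exp(-0.5 * ((times - center) / 15)^2)
        data[i, ch, ] <- data[i, ch, ] + bump
      }
    }
    epochs_set(data, times, cfg$sfreq, cfg$channels, labels,
               subject = sprintf("sub%02d", subject_index),
               artifact = artifact)
  })
}

#' Generate a full simulated experiment
#'
#' One [epochs_set()] per subject, each with per-category trial counts drawn
#' from the configured range, category-dependent evoked templates, 1/f
#' background noise, artifact trials, and optional trigger leak. Output is
#' bit-reproducible for a fixed master seed.
#'
#' @param cfg a [sim_config()].
#' @return list of `epochs_set`, one per subject.
#' @export
simulate_experiment <- function(cfg) {
  validate_sim_config(cfg)
  lapply(seq_len(cfg$n_subjects), function(s) simulate_subject(cfg, s))
}

#' Label-uninformative version of a configuration
#'
#' Returns a copy of `cfg` in which every component applies to all eight
#' categories, so the evoked template is identical across categories and
#' labels carry no information. Used for null calibration of the decoding
#' and ANOVA inference.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_config` under the global null.
#' @export
make_null_config <- function(cfg) {
  validate_sim_config(cfg)
  cfg$components <- lapply(cfg$components, function(comp) {
    comp$categories <- categories()
    comp
  })
  cfg
}
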