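# Conventional sensor-level analysis: evoked averages, sliding-window
# species x expression repeated-measures ANOVA, the >= 2 contiguous-window
# reporting rule, and planned paired contrasts.

#' Average evoked response
#'
#' Arithmetic mean over the kept trials of one condition (or a pooled set
#' of conditions, or all kept trials when `condition` is `NULL`).
#'
#' @param epochs an [epochs_set()].
#' @param condition category code(s) to average, or `NULL` for all trials.
#' @param use_kept if `TRUE` (default) only kept trials contribute.
#' @return an `evoked` object: channels x samples mean waveform with time
#'   axis, condition, subject and the number of trials averaged.
#' @export
average_evoked <- function(epochs, condition = NULL, use_kept = TRUE) {
  sel <- if (use_kept) epochs$kept else rep(TRUE, n_trials(epochs))
  if (!is.null(condition)) {
    check_categories(condition)
    sel <- sel & epochs$labels %in% condition
  }
  if (!any(sel)) {
    stopf("no kept trials for condition '%s' (subject %s)",
          paste(condition %||% "all", collapse = "+"), epochs$subject)
  }
  m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(data = m, times = epochs$times, sfreq = epochs$sfreq,
         channels = epochs$channels,
         condition = paste(condition %||% "all", collapse = "+"),
         subject = epochs$subject, n_trials = sum(sel)),
    class = "evoked"
  )
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s / %s: %d channels x %d samples (n = %d trials)\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data),
              x$n_trials))
  invisible(x)
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject evoked responses sharing the same time
#' axis and montage.
#'
#' @param evokeds list of `evoked` objects.
#' @return an `evoked` object with subject `"grand"`.
#' @export
grand_average <- function(evokeds) {
  if (length(evokeds) < 1) stopf("grand_average: empty input")
  ref <- evokeds[[1]]
  for (ev in evokeds[-1]) {
    if (!identical(ev$channels, ref$channels) ||
        length(ev$times) != length(ref$times) ||
        max(abs(ev$times - ref$times)) > 1e-9) {
      stopf("grand_average: incompatible time axes or montages")
    }
  }
  m <- Reduce(`+`, lapply(evokeds, `[[`, "data")) / length(evokeds)
  structure(
    list(data = m, times = ref$times, sfreq = ref$sfreq,
         channels = ref$channels, condition = ref$condition,
         subject = "grand", n_trials = sum(sapply(evokeds, `[[`, "n_trials"))),
    class = "evoked"
  )
}

# Two-way fully within-subject ANOVA (species 2 x expression 3) on one
# channel-window table of per-subject condition means, fitted with
# stats::aov and subject error strata. Optional Greenhouse-Geisser
# correction for the effects with more than one numerator df.
rm_anova_species_expression <- function(amp, gg = FALSE) {
  # amp: subjects x 6 matrix, columns ordered (species x expression) as
  # dog.aggressive, dog.neutral, dog.happy, human.aggressive, ...
  n <- nrow(amp)
  df_long <- data.frame(
    amp = as.vector(amp),
    subj = factor(rep(seq_len(n), 6)),
    sp = factor(rep(c("dog", "human"), each = 3 * n)),
    ex = factor(rep(rep(c("aggressive", "neutral", "happy"), each = n), 2))
  )
  a <- stats::aov(amp ~ sp * ex + Error(subj / (sp * ex)), data = df_long)
  sm <- summary(a)
  pick <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- which(trimws(rownames(tab)) == term)
    list(F = tab[i, "F value"], df1 = tab[i, "Df"],
         df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  sp <- pick("subj:sp", "sp")
  ex <- pick("subj:ex", "ex")
  int <- pick("subj:sp:ex", "sp:ex")
  adj <- function(eff, eps) {
    if (eps >= 1) return(eff$p)
    stats::pf(eff$F, eps * eff$df1, eps * eff$df2, lower.tail = FALSE)
  }
  eps_ex <- eps_int <- 1
  if (gg) {
    ex_m <- cbind(rowMeans(amp[, c(1, 4), drop = FALSE]),
                  rowMeans(amp[, c(2, 5), drop = FALSE]),
                  rowMeans(amp[, c(3, 6), drop = FALSE]))
    eps_ex <- gg_epsilon(ex_m)
    # interaction: species-difference profile across expressions
    eps_int <- gg_epsilon(amp[, 1:3, drop = FALSE] -
                            amp[, 4:6, drop = FALSE])
  }
  list(F_species = sp$F, p_species = sp$p,
       F_expression = ex$F, p_expression = adj(ex, eps_ex),
       F_interaction = int$F, p_interaction = adj(int, eps_int))
}

# Greenhouse-Geisser epsilon from the sample covariance of the repeated
# measures (k columns).
gg_epsilon <- function(x) {
  k <- ncol(x)
  S <- stats::cov(x)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (den <= 0) return(1)
  max(min(num / den, 1), 1 / (k - 1))
}

#' Sliding-window species x expression ANOVA
#'
#' Tests the six face conditions with overlapping 16-ms windows moving in
#' 4-ms steps over 0-250 ms. For every channel and window the window-mean
#' amplitude of each subject x condition enters a two-way fully
#' within-subject ANOVA with factors species (dog, human) and expression
#' (aggressive, neutral, happy).
#'
#' @param evokeds list over subjects; each element a named list of `evoked`
#'   objects, one per face condition (names `AD, ND, HD, AH, NH, HH`).
#' @param range analysis range in ms (default `c(0, 250)`); windows start
#'   at `range[1]` and must end at or before `range[2]`.
#' @param window window length in ms (default 16).
#' @param step window step in ms (default 4).
#' @param gg apply the Greenhouse-Geisser sphericity correction to the
#'   expression and interaction effects (default `FALSE`).
#' @return data frame of class `sliding_window_stats`: one row per
#'   channel x window with p-values for the species, expression and
#'   interaction effects and per-condition window-mean amplitudes.
#' @export
sliding_window_anova <- function(evokeds, range = c(0, 250), window = 16,
                                 step = 4, gg = FALSE) {
  conds <- face_categories()
  for (s in seq_along(evokeds)) {
    missing <- setdiff(conds, names(evokeds[[s]]))
    if (length(missing) > 0) {
      stopf("subject %d is missing condition(s): %s", s,
            paste(missing, collapse = ", "))
    }
  }
  ref <- evokeds[[1]][[conds[1]]]
  channels <- ref$channels
  times <- ref$times
  starts <- seq(range[1], range[2] - window, by = step)
  # cell order for the ANOVA helper: dog x (aggr, neut, happy), then human
  cell_order <- c("AD", "ND", "HD", "AH", "NH", "HH")
  n_subj <- length(evokeds)
  rows <- vector("list", length(channels) * length(starts))
  r <- 0
  for (ch_i in seq_along(channels)) {
    for (w in starts) {
      sel <- times >= w & times < w + window
      amp <- matrix(0, n_subj, 6)
      for (s in seq_len(n_subj)) {
        for (ci in seq_along(cell_order)) {
          amp[s, ci] <- mean(evokeds[[s]][[cell_order[ci]]]$data[ch_i, sel])
        }
      }
      an <- rm_anova_species_expression(amp, gg = gg)
      cm <- colMeans(amp)
      r <- r + 1
      rows[[r]] <- data.frame(
        channel = channels[ch_i], start = w, end = w + window,
        p_species = an$p_species, p_expression = an$p_expression,
        p_interaction = an$p_interaction,
        F_species = an$F_species, F_expression = an$F_expression,
        F_interaction = an$F_interaction,
        HH = cm[6], NH = cm[5], AH = cm[4],
        HD = cm[3], ND = cm[2], AD = cm[1]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sliding_window_stats", "data.frame")
  attr(out, "step") <- step
  attr(out, "window") <- window
  out
}

#' Merge contiguous significant windows
#'
#' Implements the reporting rule that only effects significant in at least
#' `min_run` consecutive (step-adjacent) sliding windows are reported;
#' qualifying runs are merged into `[first start, last end)` intervals with
#' the p-value range across the run.
#'
#' @param stats output of [sliding_window_anova()].
#' @param alpha per-window significance level (default 0.05, uncorrected).
#' @param min_run minimum run length (default 2).
#' @param effects which effects to scan.
#' @return data frame with one row per reported interval: channel, effect,
#'   start, end, number of windows, p_min, p_max.
#' @export
contiguity_filter <- function(stats, alpha = 0.05, min_run = 2,
                              effects = c("species", "expression",
                                          "interaction")) {
  step <- attr(stats, "step") %||% 4
  out <- list()
  for (eff in effects) {
    pcol <- paste0("p_", eff)
    for (ch in unique(stats$channel)) {
      sub <- stats[stats$channel == ch, ]
      sub <- sub[order(sub$start), ]
      sig <- sub[[pcol]] < alpha
      if (!any(sig)) next
      runs <- rle(sig)
      ends <- cumsum(runs$lengths)
      begins <- ends - runs$lengths + 1
      for (j in which(runs$values & runs$lengths >= min_run)) {
        idx <- begins[j]:ends[j]
        # require step-adjacency within the run (guards irregular grids)
        if (any(diff(sub$start[idx]) > step + 1e-9)) next
        out[[length(out) + 1]] <- data.frame(
          channel = ch, effect = eff,
          start = sub$start[idx[1]], end = sub$end[idx[length(idx)]],
          n_windows = length(idx),
          p_min = min(sub[[pcol]][idx]), p_max = max(sub[[pcol]][idx])
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(channel = character(), effect = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), p_min = numeric(),
                      p_max = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$channel, res$effect), , drop = FALSE]
}

#' Planned paired contrast
#'
#' Two-sided paired-samples t test between per-subject window-mean
#' amplitudes of two conditions (or pooled condition sets), on n - 1
#' degrees of freedom.
#'
#' @param x,y paired numeric vectors (one value per subject).
#' @return list with `t`, `df` and `p`.
#' @export
planned_contrast <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  if (length(x) < 2) stopf("need at least 2 paired observations")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p = 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
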