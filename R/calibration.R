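# Calibration experiments on synthetic null data: family-wise error of the
# maximum-statistics procedure and the empirical chance level of the
# permutation null.

#' Family-wise error of the maximum-statistics procedure
#'
#' Simulates replicate experiments under the global null (labels carry no
#' information: every evoked component applies to all categories), runs the
#' time-resolved decoding of several scrambled-vs-other tasks with a shared
#' label-permutation null, thresholds at the `alpha` quantile of the
#' per-permutation maxima, and reports the fraction of replicates in which
#' any cell is declared significant.
#'
#' @param n_reps number of replicate experiments.
#' @param n_tasks number of scrambled-vs-other tasks per replicate.
#' @param n_intervals number of 20-ms intervals decoded.
#' @param trials trials per condition (class) in each replicate.
#' @param n_perm permutations per replicate.
#' @param folds CV folds.
#' @param alpha family-wise level.
#' @param seed master seed.
#' @param band decoding filter band (Hz).
#' @return list with `fwer` (fraction of replicates with >= 1 significant
#'   cell), `rejected` (per-replicate logical), `thresholds` and the
#'   parameters used.
#' @export
fwer_simulation <- function(n_reps = 50, n_tasks = 3, n_intervals = 5,
                            trials = 60, n_perm = 100, folds = 5,
                            alpha = 0.05, seed = 1, band = c(2, 25)) {
  tasks <- scrambled_tasks()[seq_len(n_tasks), ]
  rejected <- logical(n_reps)
  thresholds <- numeric(n_reps)
  for (rep_i in seq_len(n_reps)) {
    cfg <- make_null_config(sim_config(
      n_subjects = 1, trials_range = c(trials, trials),
      epoch_span = c(-150, 350), artifact_prob = 0,
      seed = derive_seed(seed, 23, rep_i)))
    ep <- simulate_experiment(cfg)[[1]]
    ep <- subset_trials(ep, ep$labels %in% unique(c(tasks$a, tasks$b)))
    ep <- bandpass_filter(ep, band[1], band[2])
    binned <- bin_epochs(ep, 20)
    dtc <- time_resolved_decoding(
      binned, tasks, intervals = seq_len(n_intervals), folds = folds,
      n_perm = n_perm, seed = derive_seed(seed, 29, rep_i))
    thr <- maxstat_threshold(dtc, alpha = alpha, bonferroni_n = 1)
    thresholds[rep_i] <- thr
    rejected[rep_i] <- any(dtc$observed > thr)
  }
  list(fwer = mean(rejected), rejected = rejected,
       thresholds = thresholds, n_reps = n_reps, n_tasks = n_tasks,
       n_intervals = n_intervals, trials = trials, n_perm = n_perm,
       folds = folds, alpha = alpha, seed = seed)
}

#' Permutation-null chance calibration
#'
#' Generates one balanced two-class dataset under the global null, runs the
#' label-permutation null of the whole-epoch classifier, and summarizes the
#' pooled null accuracies: their mean (which should sit within binomial
#' error of 50%) and the central empirical chance interval.
#'
#' @param trials trials per class.
#' @param n_perm permutations.
#' @param folds CV folds.
#' @param seed master seed.
#' @param coverage coverage of the chance interval.
#' @return list with `mean_accuracy`, `chance_interval` (percent),
#'   `binomial_se` (the 0.5/sqrt(n) oracle), and the null object.
#' @export
chance_calibration <- function(trials = 100, n_perm = 200, folds = 10,
                               seed = 1, coverage = 0.95) {
  cfg <- make_null_config(sim_config(
    n_subjects = 1, trials_range = c(trials, trials),
    epoch_span = c(-150, 350), artifact_prob = 0, seed = seed))
  ep <- simulate_experiment(cfg)[[1]]
  ep <- bandpass_filter(ep, 2, 25)
  binned <- bin_epochs(ep, 20)
  task <- scrambled_tasks()[1, ]
  sel <- binned$labels %in% c(task$a, task$b)
  fm <- vectorize_features(binned, "whole")
  nul <- permutation_null(fm$x[sel, , drop = FALSE],
                          fm$labels[sel], n_perm = n_perm, folds = folds,
                          seed = seed)
  list(mean_accuracy = mean(nul$accuracies),
       chance_interval = empirical_chance_interval(nul, coverage),
       binomial_se = 0.5 / sqrt(sum(sel)),
       n_trials = sum(sel), null = nul)
}
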