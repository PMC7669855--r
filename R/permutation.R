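# Permutation inference for decoding: label-shuffled null distributions,
# empirical chance levels, maximum-statistics family-wise thresholds with
# Bonferroni correction across subjects, and the subject x task x interval
# significance matrix.

#' Label-permutation null distribution for one classifier
#'
#' Re-runs the full cross-validation after shuffling the category labels,
#' `n_perm` times. By default labels are permuted once per permutation on
#' the whole dataset before the CV loop (preserving exchangeability);
#' `scope = "train"` permutes training-fold labels only, leaving test
#' labels intact.
#'
#' @param features a [feature_matrix()] or plain numeric matrix.
#' @param labels per-trial labels when `features` is a plain matrix.
#' @param n_perm number of permutations (default 200).
#' @param folds,seed,cost,classifier,lambda,standardize as in
#'   [crossval_accuracy()].
#' @param scope `"dataset"` (default) or `"train"`.
#' @param perm_seeds optional vector of per-permutation seeds; passing the
#'   same vector to every classifier of a subject makes permutation r
#'   simultaneous across classifiers, as the maximum-statistics threshold
#'   requires.
#' @return a `permutation_null`: vector of null accuracies plus metadata.
#' @export
permutation_null <- function(features, labels = NULL, n_perm = 200,
                             folds = 10, seed = 1, cost = 1,
                             classifier = "svm", lambda = 0.05,
                             standardize = TRUE,
                             scope = c("dataset", "train"),
                             perm_seeds = NULL) {
  scope <- match.arg(scope)
  if (n_perm < 1) stopf("n_perm: must be >= 1")
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$x
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stopf("labels required with a plain matrix")
    labels <- as.character(labels)
  }
  perm_seeds <- perm_seeds %||% vapply(seq_len(n_perm), function(r)
    derive_seed(seed, 7, r), integer(1))
  if (length(perm_seeds) != n_perm) {
    stopf("perm_seeds: need one seed per permutation")
  }
  n <- length(labels)
  acc <- vapply(seq_len(n_perm), function(r) {
    y_p <- with_seed(perm_seeds[r], labels[sample.int(n)])
    if (scope == "dataset") {
      crossval_accuracy(x, y_p, folds = folds, seed = perm_seeds[r],
                        cost = cost, classifier = classifier,
                        lambda = lambda, standardize = standardize)$accuracy
    } else {
      fold_id <- make_folds(labels, folds, perm_seeds[r])
      k <- max(fold_id)
      fa <- numeric(k)
      y <- factor(labels)
      for (f in seq_len(k)) {
        tr <- fold_id != f
        pred <- fit_predict(x[tr, , drop = FALSE],
                            factor(y_p[tr], levels = levels(y)),
                            x[!tr, , drop = FALSE], cost, classifier,
                            standardize, lambda)
        fa[f] <- mean(pred == labels[!tr])
      }
      mean(fa)
    }
  }, numeric(1))
  structure(
    list(accuracies = acc, n_perm = n_perm, seed = seed,
         perm_seeds = perm_seeds, scope = scope, folds = folds,
         n_trials = n),
    class = "permutation_null"
  )
}

#' Empirical chance interval
#'
#' Central coverage interval (in percent accuracy) of the pooled null
#' accuracies across a collection of permutation nulls; the nonparametric
#' replacement of the nominal 50% chance level.
#'
#' @param nulls a `permutation_null`, a list of them, or a numeric vector
#'   of null accuracies (fractions).
#' @param coverage central coverage (default 0.95).
#' @return numeric length-2 vector `c(low, high)` in percent.
#' @export
empirical_chance_interval <- function(nulls, coverage = 0.95) {
  pooled <- pool_null_accuracies(nulls)
  if (length(pooled) < 1) stopf("need at least one null accuracy")
  lo <- (1 - coverage) / 2
  100 * unname(stats::quantile(pooled, c(lo, 1 - lo), type = 1))
}

pool_null_accuracies <- function(nulls) {
  if (inherits(nulls, "permutation_null")) return(nulls$accuracies)
  if (is.numeric(nulls)) return(as.numeric(nulls))
  unlist(lapply(nulls, pool_null_accuracies), use.names = FALSE)
}

# Lean CV loop over the interval classifiers of one task: same folds for
# every interval, linear-SVM decision values computed directly from the
# fitted weight vector. Semantics match crossval_accuracy (mean of
# per-fold accuracies, training-fold standardization).
svm_cv_multi <- function(xs, labels, fold_id, cost = 1,
                         standardize = TRUE) {
  k <- max(fold_id)
  n_int <- length(xs)
  classes <- sort(unique(labels))
  acc <- matrix(0, k, n_int)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    y_tr <- factor(labels[tr], levels = classes)
    y_te <- labels[!tr]
    for (i in seq_len(n_int)) {
      xt <- xs[[i]][tr, , drop = FALSE]
      xe <- xs[[i]][!tr, , drop = FALSE]
      if (standardize) {
        nt <- nrow(xt)
        mu <- colMeans(xt)
        sd_ <- sqrt(pmax(colSums(xt^2) - nt * mu^2, 0) / (nt - 1))
        sd_[sd_ == 0] <- 1
        xt <- sweep(sweep(xt, 2, mu, "-"), 2, sd_, "/")
        xe <- sweep(sweep(xe, 2, mu, "-"), 2, sd_, "/")
      }
      m <- e1071::svm(xt, y_tr, kernel = "linear", cost = cost,
                      scale = FALSE, fitted = FALSE)
      w <- crossprod(m$coefs, m$SV)
      d <- xe %*% t(w) - m$rho
      # libsvm orders classes by first appearance: decision > 0 is
      # m$labels[1] (verified against predict.svm)
      pred <- m$levels[ifelse(d > 0, m$labels[1], m$labels[2])]
      acc[f, i] <- mean(pred == y_te)
    }
  }
  colMeans(acc)
}

# Coerce nulls into an n_perm x n_classifiers matrix, enforcing aligned
# permutation counts.
null_matrix <- function(nulls) {
  if (is.matrix(nulls)) return(nulls)
  if (inherits(nulls, "decoding_timecourse")) {
    d <- dim(nulls$null)
    return(matrix(nulls$null, d[1], d[2] * d[3]))
  }
  if (inherits(nulls, "permutation_null")) nulls <- list(nulls)
  lens <- vapply(nulls, function(z) length(pool_null_accuracies(z)),
                 integer(1))
  if (length(unique(lens)) != 1) {
    stopf("misaligned permutation counts across classifiers: %s",
          paste(unique(lens), collapse = ", "))
  }
  do.call(cbind, lapply(nulls, pool_null_accuracies))
}

#' Maximum-statistics significance threshold
#'
#' For permutation index r, takes the maximum accuracy over all classifiers
#' (every interval and category pair of one subject), and returns the
#' empirical `1 - alpha / bonferroni_n` quantile of the maxima. The
#' quantile is the inclusive order statistic (ceiling rule), so ties break
#' conservatively. With one classifier and `bonferroni_n = 1` this reduces
#' to the simple permutation threshold.
#'
#' @param nulls aligned nulls of one subject: a `decoding_timecourse`, an
#'   n_perm x n_classifiers matrix, or a list of `permutation_null`
#'   objects sharing permutation seeds.
#' @param alpha family-wise level (default 0.05).
#' @param bonferroni_n Bonferroni factor across subjects (default 1).
#' @return the threshold accuracy (fraction).
#' @export
maxstat_threshold <- function(nulls, alpha = 0.05, bonferroni_n = 1) {
  nm <- null_matrix(nulls)
  m <- apply(nm, 1, max)
  n_perm <- length(m)
  k <- ceiling((1 - alpha / bonferroni_n) * n_perm)
  k <- max(1L, min(k, n_perm))
  sort(m)[k]
}

#' Subject-level time-resolved decoding with permutation nulls
#'
#' Runs every task's per-interval classifier on one subject's binned
#' epochs: observed cross-validated accuracies plus an `n_perm`-deep null
#' in which the same permutation stream is shared across all classifiers
#' (per permutation index), as the maximum-statistics correction requires.
#' Labels of each task are permuted once per permutation on the whole
#' dataset before the CV loop.
#'
#' @param binned a `binned_epochs` object.
#' @param tasks data frame of tasks (see [enumerate_tasks()]).
#' @param intervals bin indices to analyze (default all).
#' @param folds,cost,classifier,lambda,standardize as in
#'   [crossval_accuracy()].
#' @param n_perm number of permutations (default 200).
#' @param seed subject-level seed.
#' @return a `decoding_timecourse`: `observed` (tasks x intervals matrix),
#'   `null` (n_perm x tasks x intervals array), task ids, interval starts.
#' @export
time_resolved_decoding <- function(binned, tasks, intervals = NULL,
                                   folds = 10, n_perm = 200, seed = 1,
                                   cost = 1, classifier = "svm",
                                   lambda = 0.05, standardize = TRUE) {
  intervals <- intervals %||% seq_along(binned$bin_start)
  n_task <- nrow(tasks)
  n_int <- length(intervals)
  observed <- matrix(NA_real_, n_task, n_int,
                     dimnames = list(tasks$id, NULL))
  null <- array(NA_real_, c(n_perm, n_task, n_int))
  perm_seeds <- vapply(seq_len(n_perm), function(r)
    derive_seed(seed, 7, r), integer(1))
  for (ti in seq_len(n_task)) {
    sel <- binned$labels %in% c(tasks$a[ti], tasks$b[ti])
    labels <- binned$labels[sel]
    n <- length(labels)
    xs <- lapply(intervals, function(iv) {
      x <- binned$data[sel, , iv, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = sum(sel))
      x
    })
    run_cv <- function(y, cv_seed) {
      fold_id <- make_folds(y, folds, cv_seed)
      if (classifier == "svm") {
        svm_cv_multi(xs, y, fold_id, cost, standardize)
      } else {
        vapply(xs, function(x)
          crossval_accuracy(x, y, fold_id = fold_id, seed = cv_seed,
                            cost = cost, classifier = classifier,
                            lambda = lambda,
                            standardize = standardize)$accuracy,
          numeric(1))
      }
    }
    observed[ti, ] <- run_cv(labels, derive_seed(seed, 3, ti))
    for (r in seq_len(n_perm)) {
      y_p <- with_seed(perm_seeds[r], labels[sample.int(n)])
      null[r, ti, ] <- run_cv(y_p, perm_seeds[r])
    }
  }
  structure(
    list(observed = observed, null = null, tasks = tasks,
         intervals = intervals,
         interval_start = binned$bin_start[intervals],
         subject = binned$subject, folds = folds, n_perm = n_perm,
         seed = seed),
    class = "decoding_timecourse"
  )
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf(
    "<decoding_timecourse> %s: %d tasks x %d intervals, %d permutations\n",
    x$subject, nrow(x$observed), ncol(x$observed), x$n_perm))
  invisible(x)
}

#' Threshold observed accuracies into a significance matrix
#'
#' A cell is significant when its observed accuracy strictly exceeds the
#' subject's maximum-statistics threshold.
#'
#' @param results list of per-subject `decoding_timecourse` objects (or a
#'   single one).
#' @param alpha family-wise level (default 0.05).
#' @param bonferroni_n Bonferroni factor; defaults to the number of
#'   subjects.
#' @return a `significance_matrix`: boolean subjects x tasks x intervals
#'   array, per-subject thresholds, alpha, Bonferroni factor.
#' @export
significance_matrix <- function(results, alpha = 0.05,
                                bonferroni_n = NULL) {
  if (inherits(results, "decoding_timecourse")) results <- list(results)
  n_subj <- length(results)
  bonferroni_n <- bonferroni_n %||% n_subj
  ref <- results[[1]]
  thr <- vapply(results, maxstat_threshold, numeric(1),
                alpha = alpha, bonferroni_n = bonferroni_n)
  sig <- array(FALSE, c(n_subj, nrow(ref$observed), ncol(ref$observed)),
               dimnames = list(vapply(results, `[[`, "", "subject"),
                               ref$tasks$id, NULL))
  for (s in seq_len(n_subj)) {
    sig[s, , ] <- results[[s]]$observed > thr[s]
  }
  structure(
    list(significant = sig, thresholds = thr, alpha = alpha,
         bonferroni_n = bonferroni_n, tasks = ref$tasks,
         interval_start = ref$interval_start,
         subjects = dimnames(sig)[[1]]),
    class = "significance_matrix"
  )
}

#' @export
print.significance_matrix <- function(x, ...) {
  d <- dim(x$significant)
  cat(sprintf(
    "<significance_matrix> %d subjects x %d tasks x %d intervals; %d significant cells (alpha = %g / %d)\n",
    d[1], d[2], d[3], sum(x$significant), x$alpha, x$bonferroni_n))
  invisible(x)
}
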