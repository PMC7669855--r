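# Binary decoding of single-trial feature vectors: task enumeration,
# stratified cross-validated linear-SVM accuracy, and per-20-ms-interval
# time courses.

#' Enumerate binary classification tasks
#'
#' One task per unordered category pair: 8 categories give
#' (7 * 8) / 2 = 28 classifiers per subject.
#'
#' @param cats character vector of category codes (>= 2).
#' @return data frame with columns `a`, `b` and a task `id` of the form
#'   `"a_vs_b"`.
#' @export
#' @examples
#' nrow(enumerate_tasks(categories()))  # 28
enumerate_tasks <- function(cats = categories()) {
  cats <- unique(as.character(cats))
  if (length(cats) < 2) stopf("need at least 2 categories")
  pairs <- utils::combn(cats, 2)
  data.frame(a = pairs[1, ], b = pairs[2, ],
             id = paste(pairs[1, ], pairs[2, ], sep = "_vs_"))
}

#' The scrambled-versus-other task family
#'
#' The seven tasks discriminating the scrambled category from every other
#' category; over 8 subjects these instantiate the 56 subject x task
#' classifier families of the time-resolved analysis.
#'
#' @param cats category codes (default all 8).
#' @param reference the reference category (default `"S"`).
#' @return data frame as in [enumerate_tasks()], reference in column `b`.
#' @export
scrambled_tasks <- function(cats = categories(), reference = "S") {
  others <- setdiff(cats, reference)
  data.frame(a = others, b = reference,
             id = paste(others, reference, sep = "_vs_"))
}

#' Stratified cross-validation folds
#'
#' Seeded fold assignment that balances both classes across folds.
#'
#' @param labels per-trial class labels (2 classes).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per trial.
#' @export
make_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stopf(paste0("class '%s' has %d trials for %d folds; ",
                 "reduce the number of folds"),
          names(counts)[which.min(counts)], min(counts), k)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Fit + evaluate one classifier on one train/test split. Standardization
# statistics come from the training fold only.
fit_predict <- function(x_train, y_train, x_test, cost, classifier,
                        standardize, lambda) {
  if (standardize) {
    mu <- colMeans(x_train)
    sd_ <- apply(x_train, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    x_train <- sweep(sweep(x_train, 2, mu, "-"), 2, sd_, "/")
    x_test <- sweep(sweep(x_test, 2, mu, "-"), 2, sd_, "/")
  }
  if (classifier == "svm") {
    fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                      scale = FALSE)
    as.character(predict(fit, x_test))
  } else if (classifier == "lasso") {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stopf("classifier = 'lasso' requires the glmnet package")
    }
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                          alpha = 1, lambda = lambda)
    as.character(predict(fit, x_test, type = "class")[, 1])
  } else {
    stopf("unknown classifier '%s'", classifier)
  }
}

#' Cross-validated decoding accuracy for one binary task
#'
#' Linear-kernel support-vector classification with stratified k-fold
#' cross-validation; feature standardization statistics are estimated on
#' the training folds only. A lasso-regularized logistic regression is
#' available as an alternative classifier.
#'
#' @param features a [feature_matrix()] or plain numeric matrix.
#' @param labels per-trial labels when `features` is a plain matrix
#'   (ignored otherwise); exactly two classes after restriction.
#' @param task optional row of [enumerate_tasks()] restricting trials to
#'   the two task classes.
#' @param folds number of CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param cost SVM regularization constant C (default 1).
#' @param classifier `"svm"` (default) or `"lasso"`.
#' @param lambda lasso penalty when `classifier = "lasso"`.
#' @param standardize standardize features within folds (default `TRUE`).
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`), used to share folds across the intervals of a task.
#' @return a `classification_result`: mean CV accuracy, per-fold
#'   accuracies, per-class trial counts, hyperparameters and seed.
#' @export
crossval_accuracy <- function(features, labels = NULL, task = NULL,
                              folds = 10, seed = 1, cost = 1,
                              classifier = c("svm", "lasso"),
                              lambda = 0.05, standardize = TRUE,
                              fold_id = NULL) {
  classifier <- match.arg(classifier)
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stopf("labels required with a plain matrix")
    labels <- as.character(labels)
  }
  if (!is.null(task)) {
    sel <- labels %in% c(task$a, task$b)
    x <- x[sel, , drop = FALSE]
    labels <- labels[sel]
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    stopf("expected exactly 2 classes, got %d", length(classes))
  }
  if (is.null(fold_id)) fold_id <- make_folds(labels, folds, seed)
  k <- max(fold_id)
  y <- factor(labels, levels = classes)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    pred <- fit_predict(x[tr, , drop = FALSE], y[tr],
                        x[!tr, , drop = FALSE], cost, classifier,
                        standardize, lambda)
    fold_acc[f] <- mean(pred == labels[!tr])
  }
  structure(
    list(task = if (!is.null(task)) task$id else
           paste(classes, collapse = "_vs_"),
         accuracy = mean(fold_acc), fold_accuracy = fold_acc,
         n_per_class = as.integer(table(y)), classes = classes,
         folds = k, cost = cost, classifier = classifier,
         standardize = standardize, seed = seed),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: accuracy %.3f (%d-fold CV, n = %s)\n",
              x$task, x$accuracy, x$folds,
              paste(x$n_per_class, collapse = "/")))
  invisible(x)
}

#' Time-resolved decoding accuracies
#'
#' Trains an independent classifier on every 20-ms interval of the binned
#' epoch (feature dimension = number of channels), using the same fold
#' assignment for all intervals of the task.
#'
#' @param binned a `binned_epochs` object from [bin_epochs()].
#' @param task one row of [enumerate_tasks()].
#' @param intervals bin indices to decode (default all).
#' @param folds,seed,cost,classifier,lambda,standardize as in
#'   [crossval_accuracy()].
#' @return list of `classification_result`, one per interval, with the
#'   interval index and bin start attached.
#' @export
timecourse_accuracies <- function(binned, task, intervals = NULL,
                                  folds = 10, seed = 1, cost = 1,
                                  classifier = "svm", lambda = 0.05,
                                  standardize = TRUE) {
  intervals <- intervals %||% seq_along(binned$bin_start)
  sel <- binned$labels %in% c(task$a, task$b)
  labels <- binned$labels[sel]
  fold_id <- make_folds(labels, folds, seed)
  lapply(intervals, function(iv) {
    fm <- vectorize_features(binned, "interval", iv)
    res <- crossval_accuracy(fm$x[sel, , drop = FALSE], labels,
                             fold_id = fold_id, seed = seed, cost = cost,
                             classifier = classifier, lambda = lambda,
                             standardize = standardize)
    res$task <- task$id
    res$interval <- iv
    res$interval_start <- binned$bin_start[iv]
    res
  })
}
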