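#' Classifier configuration (RBF-kernel SVM)
#'
#' The classifier is a support vector machine with a radial-basis kernel.
#' Reported accuracies depend on its hyperparameters, so all are explicit:
#' `cost` is the soft-margin regularization weight; `gamma` the kernel width
#' (when `NULL`, the dimension-scaled rule `1/ncol(x)` is used); features are
#' standardized to zero mean/unit variance using statistics learned on the
#' training fold only.
#'
#' @param cost positive regularization weight.
#' @param gamma positive kernel width, or `NULL` for `1/ncol(x)`.
#' @param standardize standardize features on training statistics.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(cost = 1, gamma = NULL, standardize = TRUE) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, standardize = standardize),
            class = "classifier_config")
}

#' Train an SVM on labeled vectors and classify test vectors
#'
#' @param train_x,test_x numeric matrices with equal column count.
#' @param train_labels character/factor labels with exactly two classes.
#' @param config a [classifier_config()].
#' @return Character vector of predicted labels, one per test row.
#' @export
train_classify <- function(train_x, train_labels, test_x,
                           config = classifier_config()) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_labels <- as.character(train_labels)
  if (length(unique(train_labels)) < 2L) {
    stop("training data must contain both classes")
  }
  if (ncol(train_x) != ncol(test_x)) {
    stop("train/test feature dimension mismatch (", ncol(train_x), " vs ",
         ncol(test_x), ")")
  }
  if (isTRUE(config$standardize)) {
    mu <- colMeans(train_x)
    sd_ <- apply(train_x, 2L, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    train_x <- sweep(sweep(train_x, 2L, mu), 2L, sd_, "/")
    test_x <- sweep(sweep(test_x, 2L, mu), 2L, sd_, "/")
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(train_x) else config$gamma
  fit <- e1071::svm(train_x, factor(train_labels), kernel = "radial",
                    cost = config$cost, gamma = gamma, scale = FALSE)
  as.character(stats::predict(fit, test_x))
}

#' Confusion-matrix counts and the five derived rates
#'
#' @param TP,FP,TN,FN non-negative integer counts, total > 0.
#' @return An object of class `confusion_metrics` with the counts and
#'   `accuracy = (TP+TN)/total`, `sensitivity = TP/(TP+FN)`,
#'   `specificity = TN/(TN+FP)`, `ppv = TP/(TP+FP)`, `npv = TN/(TN+FN)`.
#'   A rate with a zero denominator is `NA`.
#' @export
#' @examples
#' confusion_metrics(TP = 97, FP = 0, TN = 200, FN = 3)
confusion_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN,
         accuracy = (TP + TN) / total,
         sensitivity = rate(TP, TP + FN),
         specificity = rate(TN, TN + FP),
         ppv = rate(TP, TP + FP),
         npv = rate(TN, TN + FN)),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> TP %d FP %d TN %d FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  ppv %.4f  npv %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

.metrics_from_predictions <- function(truth, predicted) {
  pos <- "seizure"
  confusion_metrics(
    TP = sum(truth == pos & predicted == pos),
    FP = sum(truth != pos & predicted == pos),
    TN = sum(truth != pos & predicted != pos),
    FN = sum(truth == pos & predicted != pos)
  )
}

#' Cross-validation scheme descriptor
#'
#' @param type `"loso"` (leave-one-subject-out) or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed seed for the (stratified) fold shuffle of `"kfold"`.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(type = c("loso", "kfold"), k = 10L, seed = 1L) {
  type <- match.arg(type)
  if (type == "kfold") stopifnot(k >= 2)
  structure(list(type = type, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

# fold assignment: integer fold id per observation (NA = never test)
.make_folds <- function(labels, subjects, scheme) {
  n <- length(labels)
  if (scheme$type == "loso") {
    subj <- sort(unique(subjects))
    if (length(subj) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
    return(match(subjects, subj))
  }
  k <- scheme$k
  if (n < k) stop("need at least k observations for k-fold CV")
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed), add = TRUE)
  set.seed(scheme$seed)
  fold <- integer(n)
  if (min(table(labels)) < k) {
    warning("a class has fewer than k members; using a plain shuffled split")
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  } else {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  }
  fold
}

# pooled-CV engine on a precomputed feature matrix
.run_cv <- function(x, labels, folds, config) {
  stopifnot(nrow(x) == length(labels), length(folds) == length(labels))
  truth <- character(0); pred <- character(0)
  skipped <- 0L
  for (f in sort(unique(folds))) {
    test_i <- which(folds == f)
    train_i <- which(folds != f)
    if (length(unique(labels[train_i])) < 2L) {
      warning("fold ", f, " skipped: training data has a single class")
      skipped <- skipped + 1L
      next
    }
    p <- train_classify(x[train_i, , drop = FALSE], labels[train_i],
                        x[test_i, , drop = FALSE], config)
    truth <- c(truth, labels[test_i]); pred <- c(pred, p)
  }
  if (length(truth) == 0L) stop("all CV folds were skipped")
  .metrics_from_predictions(truth, pred)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: that subject's segments form the test set and all
#' other subjects' segments the training set, so no subject contributes to
#' both sides of a fold. Predictions are pooled over folds into a single
#' confusion matrix (micro-averaging).
#'
#' @param segments list of [eeg_segment]s (>= 2 subjects).
#' @param featurizer function mapping a list of segments to a numeric matrix
#'   with one row per segment.
#' @param config a [classifier_config()].
#' @return A [confusion_metrics()] object.
#' @export
leave_one_subject_out_cv <- function(segments, featurizer,
                                     config = classifier_config()) {
  x <- featurizer(segments)
  labels <- vapply(segments, `[[`, "", "label")
  subjects <- vapply(segments, `[[`, "", "subject_id")
  folds <- .make_folds(labels, subjects, cv_scheme("loso"))
  .run_cv(x, labels, folds, config)
}

#' Stratified k-fold cross-validation
#'
#' Folds preserve the class ratio to within one segment per fold (degrading
#' to a plain shuffled split, with a warning, when a class has fewer than
#' `k` members). Predictions are pooled over folds into a single confusion
#' matrix.
#'
#' @param segments list of [eeg_segment]s.
#' @param k number of folds (`k = n` gives leave-one-out).
#' @param featurizer function mapping a list of segments to a numeric matrix.
#' @param config a [classifier_config()].
#' @param seed seed for the fold shuffle.
#' @return A [confusion_metrics()] object.
#' @export
kfold_cv <- function(segments, k = 10L, featurizer,
                     config = classifier_config(), seed = 1L) {
  x <- featurizer(segments)
  labels <- vapply(segments, `[[`, "", "label")
  folds <- .make_folds(labels, NULL, cv_scheme("kfold", k = k, seed = seed))
  .run_cv(x, labels, folds, config)
}
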