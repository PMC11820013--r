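#' Threshold-based binary classification metrics
#'
#' Computes accuracy, specificity (TN / (TN + FP)), recall
#' (TP / (TP + FN)), precision, and F1 from labels and predicted
#' probabilities at a decision threshold (prediction positive when
#' `prob >= threshold`). F1 is defined as 0 when precision + recall is 0.
#'
#' @param labels 0/1 vector.
#' @param probs numeric vector of the same length, in \[0, 1\].
#' @param threshold decision threshold, default 0.5.
#' @return Named numeric vector: accuracy, specificity, recall,
#'   precision, f1.
#' @export
binary_metrics <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(accuracy = (tp + tn) / length(labels),
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    recall = rec,
    precision = prec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

#' Area under the ROC curve
#'
#' The Mann–Whitney concordance probability: the chance that a randomly
#' chosen positive outranks a randomly chosen negative, ties counting
#' one half. Computed exactly through midranks.
#'
#' @param labels 0/1 vector containing both classes.
#' @param probs numeric scores of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, probs) {
  if (length(labels) != length(probs)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC")
  r <- rank(probs)   # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that every sample is
#' validated exactly once and each class is spread as evenly as possible
#' across folds. Deterministic in `seed`.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    pool <- which(labels == cl)
    pool <- pool[sample.int(length(pool))]
    fold[pool] <- rep_len(seq_len(k), length(pool))
  }
  fold
}

#' Cross-validated evaluation of the model
#'
#' Stratified k-fold cross-validation at the bag (slide) level: each fold
#' in turn is held out, a fresh model is fitted on the remaining bags
#' (with its own internal early-stopping split), and the held-out fold is
#' scored. Reports per-fold metrics and their mean and standard deviation.
#'
#' @param bags list of [mil_bag()] objects.
#' @param folds number of folds (default 10). Every fold's validation
#'   part must contain both classes.
#' @param seed seed driving fold assignment and all per-fold fits.
#' @param threshold decision threshold for the thresholded metrics.
#' @param ... passed on to [camil()] (e.g. `epochs`, `fusion`,
#'   `dim_model`).
#' @return Object of class `camil_cv`: list with `per_fold` (data.frame),
#'   `mean`, `sd`, `fold_assignment`.
#' @export
cross_validate <- function(bags, folds = 10L, seed = 1L, threshold = 0.5,
                           ...) {
  ys <- vapply(bags, function(b) b$label, numeric(1))
  fold <- stratified_folds(ys, k = folds, seed = seed)
  if (any(tabulate(fold[ys == 1], folds) == 0) ||
      any(tabulate(fold[ys == 0], folds) == 0)) {
    stop("infeasible stratification: some fold lacks a class")
  }
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- bags[fold == f]
    train <- bags[fold != f]
    fit <- camil(train, threshold = threshold,
                 seed = as.integer(seed) + f, ...)
    probs <- predict(fit, test)
    yte <- vapply(test, function(b) b$label, numeric(1))
    m <- binary_metrics(yte, probs, threshold = threshold)
    rows[[f]] <- data.frame(fold = f, t(m), auc = auc_score(yte, probs))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[metric_cols]),
                 sd = vapply(per_fold[metric_cols], stats::sd, numeric(1)),
                 fold_assignment = fold),
            class = "camil_cv")
}

#' @export
print.camil_cv <- function(x, digits = 3, ...) {
  k <- nrow(x$per_fold)
  cat(k, "-fold cross-validation (mean ± sd over folds):\n", sep = "")
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s %.*f ± %.*f\n", nm, digits, x$mean[[nm]],
                digits, x$sd[[nm]]))
  }
  invisible(x)
}
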