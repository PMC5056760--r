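#' Confusion counts from predicted and true labels
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return a named list of the four counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  as.list(counts)
}

#' Sensitivity (recall): TP / (TP + FN)
#' @param c confusion counts from [confusion_counts()].
#' @return numeric; `NaN` if no positives.
#' @export
sensitivity <- function(c) {
  c <- do.call(confusion_counts, c[c("TP", "TN", "FP", "FN")])
  c$TP / (c$TP + c$FN)
}

#' Specificity: TN / (TN + FP)
#' @inheritParams sensitivity
#' @return numeric; `NaN` if no negatives.
#' @export
specificity <- function(c) {
  c <- do.call(confusion_counts, c[c("TP", "TN", "FP", "FN")])
  c$TN / (c$TN + c$FP)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' when any marginal is empty (zero denominator).
#'
#' @inheritParams sensitivity
#' @return numeric in \[-1, 1\].
#' @export
mcc <- function(c) {
  c <- do.call(confusion_counts, c[c("TP", "TN", "FP", "FN")])
  # products overflow integer range on large test sets: compute in double
  tp <- as.numeric(c$TP); tn <- as.numeric(c$TN)
  fp <- as.numeric(c$FP); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

check_labels <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  labels
}

#' Empirical ROC curve
#'
#' Points (FPR, TPR) swept over every distinct score threshold, from (0,0)
#' to (1,1), with the decision rule "predict positive when score >=
#' threshold".
#'
#' @param scores numeric prediction scores (larger = more likely positive).
#' @param labels 0/1 (or logical) true labels; both classes required.
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes required for a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cut <- c(which(diff(s) != 0), length(s))   # block ends of tied scores
  tp <- cumsum(l)[cut]; fp <- cumsum(1L - l)[cut]
  data.frame(threshold = c(Inf, s[cut]),
             fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve
#'
#' Computed with the rank statistic (Mann-Whitney form): the fraction of
#' positive/negative pairs ranked correctly, ties counted 1/2. This equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return numeric AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- as.numeric(sum(labels == 1L))   # doubles: n_pos * n_neg can
  n_neg <- as.numeric(sum(labels == 0L))   # overflow integer range
  if (n_pos == 0 || n_neg == 0) stopf("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical precision-recall curve
#'
#' Precision against recall over descending score thresholds (tied scores
#' form one threshold block).
#'
#' @inheritParams roc_curve
#' @return `data.frame` with columns `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stopf("at least one positive required for a PR curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  cut <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[cut]; pred <- cut
  data.frame(threshold = s[cut], recall = tp / n_pos, precision = tp / pred)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation: each threshold block contributes
#' its recall increment times the precision at that block.
#'
#' @inheritParams roc_curve
#' @return numeric AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  pr <- pr_curve(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Summarize scored predictions at a decision threshold
#' @param scores,labels as in [roc_curve()].
#' @param threshold predict positive when `score >= threshold`.
#' @return list with confusion counts and sensitivity/specificity/MCC.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  labels <- check_labels(scores, labels)
  pred <- scores >= threshold
  cc <- confusion_counts(TP = sum(pred & labels == 1L),
                         TN = sum(!pred & labels == 0L),
                         FP = sum(pred & labels == 0L),
                         FN = sum(!pred & labels == 1L))
  c(cc, list(sensitivity = sensitivity(cc), specificity = specificity(cc),
             mcc = mcc(cc)))
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin so fold sizes differ by <= 1 per class
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (k > length(idx))
        stopf("k = %d exceeds class size %d", k, length(idx))
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the labeled set into k stratified folds; within each training
#' fold the scaler (and, if grids are supplied, the grid search) is refit
#' from scratch so no information leaks into the held-out fold. Out-of-fold
#' scores are pooled into a single report.
#'
#' @param X feature matrix (rows = sites).
#' @param labels 0/1 labels per row.
#' @param k number of folds (default 5).
#' @param config pipeline configuration from [pipeline_config()].
#' @param seed optional integer seed for the fold assignment.
#' @return an evaluation report (see [evaluation_report()]) plus the
#'   per-row out-of-fold `scores` and `fold` assignment.
#' @export
kfold_cv <- function(X, labels, k = 5L, config = pipeline_config(),
                     seed = NULL) {
  labels <- check_labels(seq_along(labels), labels)
  if (k < 2L) stopf("k must be >= 2")
  fold <- stratified_folds(labels, k, seed = seed)
  scores <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_svm_pipeline(X[tr, , drop = FALSE], labels[tr], config,
                            seed = derive_seed(seed, f))
    scores[!tr] <- svm_pipeline_scores(fit, X[!tr, , drop = FALSE])
  }
  rep <- evaluation_report(scores, labels)
  rep$fold <- fold
  rep$scores <- scores
  rep
}

#' Assemble a full evaluation report from scores and labels
#'
#' @inheritParams roc_curve
#' @param thresholds optional named numeric vector of decision thresholds
#'   (e.g. a stringency [ThresholdTable][calibrate_thresholds]); per-level
#'   confusion counts and metrics are included when supplied.
#' @return list with `auroc`, `aupr`, `roc`, `pr`, `n_pos`, `n_neg`,
#'   `ratio`, and optional `by_level` metrics.
#' @export
evaluation_report <- function(scores, labels, thresholds = NULL) {
  labels <- check_labels(scores, labels)
  rep <- list(n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
              ratio = sum(labels == 0L) / max(1L, sum(labels == 1L)),
              auroc = auroc(scores, labels), aupr = aupr(scores, labels),
              roc = roc_curve(scores, labels), pr = pr_curve(scores, labels))
  if (!is.null(thresholds)) {
    rep$by_level <- lapply(thresholds, function(t)
      threshold_metrics(scores, labels, t))
  }
  rep
}

#' Evaluate a trained predictor on an independent labeled test set
#'
#' Scores every labeled site with the predictor and reports AUROC, AUPR,
#' curves, and sensitivity/specificity/MCC at each stored stringency level.
#'
#' @param predictor a trained predictor from [train_predictor()].
#' @param test_sites labeled-site `data.frame`.
#' @param trans transcript `data.frame` the sites refer to.
#' @param seed optional seed for the structure-feature shuffles.
#' @return evaluation report (see [evaluation_report()]).
#' @export
evaluate_independent <- function(predictor, test_sites, trans, seed = NULL) {
  X <- build_feature_matrix(test_sites, trans, mode = predictor$mode,
                            n_shuffles = predictor$config$n_shuffles,
                            seed = seed, positional_flank = predictor$positional_flank)
  scores <- predict_scores(predictor, X)
  labels <- as.integer(test_sites$label == "positive")
  thr <- vapply(predictor$thresholds, function(x) x$threshold, 0)
  evaluation_report(scores, labels, thresholds = thr)
}
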