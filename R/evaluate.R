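## Method-agnostic evaluation: pooled ROC/AUC over (cell, trial)
## decisions, cost-thresholded confusion matrices, stratified k-fold
## cross-validation and train/test mismatch experiments.

pool_scores <- function(scores, truths) {
  s <- as.vector(as.matrix(scores))
  y <- as.vector(as.matrix(truths))
  if (length(s) != length(y)) {
    stop_invalid("`scores` and `truths` must have the same number of entries")
  }
  keep <- is.finite(s) & !is.na(y)
  list(s = s[keep], y = as.numeric(y[keep] > 0))
}

#' Pooled ROC curve and AUC
#'
#' Pools every (off-diagonal cell, trial) pair into one binary scoring
#' problem, sweeps the classification threshold over the unique score
#' values jointly for all cells, and returns the ROC curve and its
#' trapezoidal AUC (ties receive half credit, as in the Mann-Whitney
#' statistic). This joint-threshold pooling makes multiclass MBC, per-cell
#' CBC and the GCA baseline directly comparable on one curve.
#'
#' @param scores numeric matrix (trials x cells) or vector of scores;
#'   higher means stronger evidence for a link.
#' @param truths binary matrix or vector of the same shape: the true
#'   graph entries.
#' @return A `roc_curve`: list with `points` (data frame of `fpr`, `tpr`
#'   along the sweep, starting at (0, 0) and ending at (1, 1)), `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, truths) {
  po <- pool_scores(scores, truths)
  n_pos <- sum(po$y == 1)
  n_neg <- sum(po$y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid("AUC undefined: pooled truths are single-class")
  }
  ord <- order(po$s, decreasing = TRUE)
  s <- po$s[ord]
  y <- po$y[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last_of_tie <- c(diff(s) != 0, TRUE)
  tpr <- tp[last_of_tie] / n_pos
  fpr <- fp[last_of_tie] / n_neg
  auc <- sum(diff(c(0, fpr)) * (c(0, head(tpr, -1)) + tpr) / 2)
  structure(
    list(points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_curve")
}

#' @exportS3Method base::print
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Row-normalized confusion matrix at a fixed threshold
#'
#' Binarizes the pooled cell scores at `threshold` and tabulates them
#' against the pooled truths. Percentages are row-normalized: the true-1
#' row splits into (TP%, FN%), the true-0 row into (FP%, TN%).
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold; the default 0.75 is the
#'   indifference point of the +1 true-positive / -3 false-positive cost
#'   model (see [predict_graph()]).
#' @return A `confusion_report`: list with `percent` (2 x 2 row-normalized
#'   matrix), `counts`, `threshold`.
#' @export
confusion_at_threshold <- function(scores, truths, threshold = 0.75) {
  threshold <- check_prob(threshold, "threshold")
  po <- pool_scores(scores, truths)
  if (length(po$s) == 0) stop_invalid("empty score pool")
  pred <- as.numeric(po$s > threshold)
  counts <- matrix(
    c(sum(po$y == 1 & pred == 1), sum(po$y == 1 & pred == 0),
      sum(po$y == 0 & pred == 1), sum(po$y == 0 & pred == 0)),
    2, 2, byrow = TRUE,
    dimnames = list(true = c("1", "0"), pred = c("1", "0")))
  percent <- 100 * counts / pmax(rowSums(counts), 1)
  structure(list(percent = percent, counts = counts, threshold = threshold),
            class = "confusion_report")
}

#' @exportS3Method base::print
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion matrix at threshold %.2f (row-normalized %%):\n",
              x$threshold))
  print(round(x$percent, 1))
  invisible(x)
}

## Stratified fold assignment: within each graph class, replicates are
## shuffled and dealt round-robin, so every class appears in every
## training split whenever trials_per_graph >= folds.
stratified_folds <- function(graph_index, folds, seed) {
  fold <- integer(length(graph_index))
  with_seed(mix_seed(seed, 7L), {
    for (g in unique(graph_index)) {
      idx <- which(graph_index == g)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

new_report <- function(method, mode, engineered, roc, scores, truths,
                       datasets, folds, seed, extra = list()) {
  structure(
    c(list(method = method, mode = mode, engineered = engineered,
           auc = roc$auc, roc = roc, scores = scores, truths = truths,
           datasets = datasets, folds = folds, seed = seed), extra),
    class = "experiment_report")
}

#' @exportS3Method base::print
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %s (%s%s) on %s -- AUC = %.4f\n",
              toupper(x$method), x$mode,
              if (isTRUE(x$engineered)) ", engineered" else "",
              paste(x$datasets, collapse = " -> "), x$auc))
  invisible(x)
}

#' Cross-validated pooled AUC of a causal-inference method
#'
#' For the supervised methods (CBC, MBC) the dataset is split into
#' stratified-by-graph folds; each fold is scored by a model trained on
#' the remaining folds, held-out cell scores are pooled across folds, and
#' the pooled ROC/AUC is computed against the true graphs. The GCA
#' baseline needs no training: its scores are computed per trial and
#' pooled directly.
#'
#' @param dataset a labeled `mar_dataset`.
#' @param method `"cbc"`, `"mbc"` or `"gca"`.
#' @param mode scenario family for featurization (supervised methods).
#' @param engineered use engineered feature expansions.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param reg_strength inverse regularization strength C.
#' @param features optional precomputed [featurize_dataset()] result for
#'   `dataset` (must match `mode`/`engineered`); avoids refitting the
#'   feature map when several methods share it.
#' @return An `experiment_report` with the pooled `roc`, `auc`, held-out
#'   `scores` and `truths`.
#' @export
crossval_auc <- function(dataset, method = c("cbc", "mbc", "gca"),
                         mode = "complete", engineered = TRUE,
                         folds = 5L, seed = 1L, reg_strength = 1,
                         features = NULL) {
  method <- match.arg(method)
  folds <- check_count(folds, "folds", min = 2L)
  truths <- dataset_truth(dataset)
  ds_id <- sprintf("%s(seed=%d)", dataset$noise_mode, dataset$seed)
  if (method == "gca") {
    scores <- gca_scores(dataset)
    roc <- roc_auc(scores, truths)
    return(new_report("gca", "c-pw", FALSE, roc, scores, truths,
                      ds_id, folds = NA_integer_, seed = seed))
  }
  feats <- features_for(dataset, mode, engineered, features)
  gi <- feats$graph_index
  fold <- stratified_folds(gi, folds, seed)
  scores <- matrix(NA_real_, nrow(feats$X), ncol(truths),
                   dimnames = list(NULL, colnames(truths)))
  for (f in seq_len(folds)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    if (length(te_idx) == 0L) next
    tr_feats <- subset_features(feats, tr_idx)
    model <- if (method == "cbc") {
      train_cbc(tr_feats, reg_strength = reg_strength, seed = mix_seed(seed, f))
    } else {
      train_mbc(tr_feats, reg_strength = reg_strength, seed = mix_seed(seed, f))
    }
    scores[te_idx, ] <- predict_cell_scores(model, subset_features(feats, te_idx))
  }
  roc <- roc_auc(scores, truths)
  new_report(method, mode, engineered, roc, scores, truths, ds_id,
             folds = folds, seed = seed)
}

features_for <- function(dataset, mode, engineered, features) {
  if (is.null(features)) {
    return(featurize_dataset(dataset, mode = mode, engineered = engineered))
  }
  check_features(features)
  if (!identical(features$mode, mode) ||
      !identical(isTRUE(features$engineered), isTRUE(engineered)) ||
      nrow(features$X) != length(dataset$trials)) {
    stop_invalid("precomputed `features` do not match the requested configuration")
  }
  features
}

subset_features <- function(feats, idx) {
  out <- feats
  out$X <- feats$X[idx, , drop = FALSE]
  out$graph_index <- feats$graph_index[idx]
  out
}

#' AUC under a generative-process mismatch
#'
#' Trains a supervised model once on `train_dataset` and scores every
#' trial of `test_dataset` (e.g. train on noiseless data, test on noisy
#' data). Both datasets must share `M` and the feature configuration.
#'
#' @param train_dataset,test_dataset labeled `mar_dataset` objects with
#'   identical `M` and `p`.
#' @inheritParams crossval_auc
#' @param method `"cbc"` or `"mbc"`.
#' @param train_features,test_features optional precomputed features.
#' @return An `experiment_report`.
#' @export
mismatch_auc <- function(train_dataset, test_dataset,
                         method = c("cbc", "mbc"), mode = "complete",
                         engineered = TRUE, seed = 1L, reg_strength = 1,
                         train_features = NULL, test_features = NULL) {
  method <- match.arg(method)
  if (train_dataset$M != test_dataset$M || train_dataset$p != test_dataset$p) {
    stop_invalid("train and test datasets must share M and p")
  }
  tr <- features_for(train_dataset, mode, engineered, train_features)
  te <- features_for(test_dataset, mode, engineered, test_features)
  model <- if (method == "cbc") {
    train_cbc(tr, reg_strength = reg_strength, seed = seed)
  } else {
    train_mbc(tr, reg_strength = reg_strength, seed = seed)
  }
  scores <- predict_cell_scores(model, te)
  truths <- dataset_truth(test_dataset)
  roc <- roc_auc(scores, truths)
  new_report(method, mode, engineered, roc, scores, truths,
             c(sprintf("train:%s(seed=%d)", train_dataset$noise_mode,
                       train_dataset$seed),
               sprintf("test:%s(seed=%d)", test_dataset$noise_mode,
                       test_dataset$seed)),
             folds = NA_integer_, seed = seed)
}
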