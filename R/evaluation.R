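# Evaluation: one-vs-rest confusion counting with a rejection option, ROC
# threshold sweeps, and stratified cross-validation.
#
# In the multiclass-as-binary protocol one class is designated positive and
# the rest jointly negative. Rejected (unclassified) positives count as
# false negatives; negatives confused with other negative classes, and
# rejected negatives, count as true negatives — they were, after all, kept
# out of the positive class. Totals tp+fn and fp+tn are therefore invariant
# to the rejection threshold.

#' One-vs-rest confusion counts with rejection
#'
#' @param truth character vector of true class labels.
#' @param predicted character vector of predicted labels; may contain
#'   [UNCLASSIFIED].
#' @param positive_class the label treated as positive; all other true
#'   labels are jointly negative.
#' @return Named list with integer counts `tp`, `fp`, `tn`, `fn`.
#' @export
one_vs_rest_counts <- function(truth, predicted, positive_class) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("truth and predicted disagree in length")
  if (!positive_class %in% truth) {
    stop("positive class '", positive_class, "' is absent from the true labels")
  }
  pos <- truth == positive_class
  pred_pos <- predicted == positive_class
  list(
    tp = sum(pos & pred_pos),
    fp = sum(!pos & pred_pos),
    tn = sum(!pos & !pred_pos),
    fn = sum(pos & !pred_pos)
  )
}

#' False and true positive rates
#'
#' `FPR = FP / (FP + TN)` and `TPR = TP / (TP + FN)`.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see
#'   [one_vs_rest_counts()]).
#' @return Named list with `fpr` and `tpr`.
#' @export
rates <- function(counts) {
  if ((counts$fp + counts$tn) == 0 || (counts$tp + counts$fn) == 0) {
    stop("rates undefined: a class has no instances")
  }
  list(
    fpr = counts$fp / (counts$fp + counts$tn),
    tpr = counts$tp / (counts$tp + counts$fn)
  )
}

#' ROC sweep over rejection thresholds
#'
#' Posteriors are computed once; each threshold then relabels instances
#' whose maximum posterior falls below it as [UNCLASSIFIED], and one-vs-rest
#' counts are taken per the rejection rules. The default grid is 0.30 to
#' 0.99 in steps of 0.01 (70 points).
#'
#' @param model an `mcrum` model.
#' @param data a [labeled_dataset()].
#' @param positive_class the class treated as positive.
#' @param decoder `"naive"` or `"gbt"` (hard decoding has no posterior to
#'   threshold).
#' @param thresholds numeric vector of rejection thresholds.
#' @return Data frame with columns `threshold`, `fpr`, `tpr` and
#'   `unclassified_fraction`.
#' @export
roc_sweep <- function(model, data, positive_class,
                      decoder = c("naive", "gbt"),
                      thresholds = seq(0.30, 0.99, by = 0.01)) {
  decoder <- match.arg(decoder)
  stopifnot(inherits(data, "labeled_dataset"))
  if (any(thresholds < 0 | thresholds >= 1)) stop("thresholds must lie in [0, 1)")
  pred <- predict_mcrum(model, data$features, decoder = decoder, threshold = 0)
  idx <- max.col(pred$posterior, ties.method = "first")
  maxp <- pred$posterior[cbind(seq_along(idx), idx)]
  argmax <- model$class_names[idx]
  out <- lapply(thresholds, function(t) {
    lab <- ifelse(maxp >= t, argmax, UNCLASSIFIED)
    cnt <- one_vs_rest_counts(data$labels, lab, positive_class)
    rt <- rates(cnt)
    data.frame(
      threshold = t, fpr = rt$fpr, tpr = rt$tpr,
      unclassified_fraction = mean(lab == UNCLASSIFIED)
    )
  })
  do.call(rbind, out)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over the folds. The dealing position rolls over from class to
# class so every fold is used even when folds exceed the per-class count
# (e.g. leave-one-out).
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  offset <- 0L
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  assignment
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold on the remaining data and reports per-fold
#' accuracy. With `threshold = 0` no instance is rejected; with a positive
#' threshold, rejected instances count as errors.
#'
#' @param data a [labeled_dataset()].
#' @param folds number of folds (>= 2).
#' @param code,M,gamma,standardize passed to [train_mcrum()].
#' @param decoder decoder used for prediction.
#' @param threshold rejection threshold.
#' @param seed integer seed for the fold split and training.
#' @param ... further arguments to [train_mcrum()].
#' @return List with `fold_accuracy`, `mean`, `sd` and the fold
#'   `assignment`.
#' @export
cross_validate <- function(data, folds = 10L, code = "ap",
                           decoder = c("naive", "gbt", "hard"),
                           M = "auto", gamma = "auto", standardize = TRUE,
                           threshold = 0, seed = 1L, ...) {
  decoder <- match.arg(decoder)
  stopifnot(inherits(data, "labeled_dataset"))
  if (folds < 2L) stop("folds must be at least 2")
  assignment <- stratified_folds(data$labels, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    train_idx <- which(assignment != f)
    test_idx <- which(assignment == f)
    train <- labeled_dataset(
      data$features[train_idx, , drop = FALSE], data$labels[train_idx],
      class_names = data$class_names
    )
    if (length(unique(train$labels)) < length(data$class_names) ||
        length(test_idx) == 0L) {
      stop("fold ", f, " is missing a class; use fewer folds")
    }
    model <- train_mcrum(
      train,
      code = code, M = M, gamma = gamma,
      seed = seed, standardize = standardize, ...
    )
    pred <- predict_mcrum(
      model, data$features[test_idx, , drop = FALSE],
      decoder = decoder, threshold = threshold
    )
    acc[f] <- mean(pred$label == data$labels[test_idx])
  }
  list(
    fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
    assignment = assignment
  )
}
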