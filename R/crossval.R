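## Cross-validated and cross-condition performance estimation.

#' Stratified fold assignment
#'
#' Seeded shuffle within each class, round-robin assignment to folds: fold
#' sizes differ by at most one per class.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) per trial.
#' @export
stratified_folds <- function(labels, k, seed) {
  lab <- as.factor(labels)
  if (min(table(lab)) < k) {
    stop_invalid(sprintf(
      "smallest class has %d trials, fewer than k = %d folds; use a smaller k",
      min(table(lab)), k))
  }
  folds <- integer(length(lab))
  with_seed(seed, {
    for (j in seq_along(levels(lab))) {
      idx <- which(lab == levels(lab)[j])
      idx <- idx[sample.int(length(idx))]
      ## rotate the round-robin start per class so the leftover trials land
      ## in different folds and total fold sizes differ by at most one
      folds[idx] <- ((seq_along(idx) + j - 2L) %% k) + 1L
    }
  })
  folds
}

#' Ten-fold cross-validated classification accuracy
#'
#' Stratified seeded split into `k` folds; for each fold the regularization
#' strength is grid-searched on the k-1 training folds (nested selection by
#' default, preventing selection bias; `selection = "flat"` selects once on
#' all trials with the simpler single-loop scheme), the classifier is fitted
#' on the training folds and evaluated on the held-out fold. A trial's own
#' fold is never used for training its prediction.
#'
#' @param features `feature_matrix` or trials x features matrix.
#' @param labels Binary labels, at least `k` trials per class.
#' @param k Folds (default 10).
#' @param seed Integer seed (fold split and inner selection).
#' @param selection "nested" (default) or "flat" lambda selection.
#' @return A `cv_result`: `overall_accuracy` (fraction of all held-out
#'   trials correct), `fold_accuracies`, `predictions`, `decision_values`
#'   (per trial, from its held-out fold), `chosen_lambda` per fold, `folds`,
#'   `seed`.
#' @export
crossval_accuracy <- function(features, labels, k = 10, seed = 1,
                              selection = c("nested", "flat")) {
  selection <- match.arg(selection)
  fm_meta <- NULL
  if (inherits(features, "feature_matrix")) {
    fm_meta <- features$meta
    features <- features$values
  }
  lab <- as.factor(labels)
  folds <- stratified_folds(lab, k, seed)

  flat_lambda <- if (selection == "flat") {
    select_lambda(features, lab, derive_seed(seed, "flat-select"))
  } else {
    NULL
  }

  predictions <- factor(rep(levels(lab)[1], length(lab)), levels = levels(lab))
  decision_values <- numeric(length(lab))
  chosen <- numeric(k)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    lam <- if (selection == "nested") {
      select_lambda(features[tr, , drop = FALSE], lab[tr],
                    derive_seed(seed, paste0("inner-fold", f)))
    } else {
      flat_lambda
    }
    fit <- fit_rllr(features[tr, , drop = FALSE], lab[tr], as.numeric(lam))
    te <- which(!tr)
    predictions[te] <- predict(fit, features[te, , drop = FALSE])
    decision_values[te] <- predict(fit, features[te, , drop = FALSE], type = "decision")
    chosen[f] <- as.numeric(lam)
    fold_acc[f] <- mean(predictions[te] == lab[te])
  }
  structure(list(overall_accuracy = mean(predictions == lab),
                 fold_accuracies = fold_acc,
                 predictions = predictions,
                 decision_values = decision_values,
                 chosen_lambda = chosen,
                 folds = folds,
                 labels = lab,
                 feature_meta = fm_meta,
                 k = k, seed = seed, selection = selection),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: overall accuracy %.1f%% (folds %.0f-%.0f%%)\n",
              x$k, 100 * x$overall_accuracy,
              100 * min(x$fold_accuracies), 100 * max(x$fold_accuracies)))
  invisible(x)
}

#' Cross-condition transfer accuracy
#'
#' Selects lambda and fits on all training trials, evaluates once on all
#' test trials (no cross-validation: train and test are different
#' conditions by design). Training standardization is reused on the test
#' features. Feature layouts must match.
#'
#' @param train_features,train_labels Training data (e.g. actual-vs-none).
#' @param test_features,test_labels Test data (e.g. attempted-vs-none).
#' @param seed Integer seed for the lambda-selection folds.
#' @return List: `accuracy`, `decision_values`, `predictions`, `model`.
#' @export
transfer_accuracy <- function(train_features, train_labels,
                              test_features, test_labels, seed = 1) {
  tr_meta <- if (inherits(train_features, "feature_matrix")) train_features$meta else NULL
  te_meta <- if (inherits(test_features, "feature_matrix")) test_features$meta else NULL
  if (!is.null(tr_meta) && !is.null(te_meta) && !identical(tr_meta, te_meta)) {
    stop_invalid("train and test feature metadata (channels/frequencies/windows) differ")
  }
  trX <- if (inherits(train_features, "feature_matrix")) train_features$values else train_features
  teX <- if (inherits(test_features, "feature_matrix")) test_features$values else test_features
  if (ncol(trX) != ncol(teX)) stop_invalid("train and test feature counts differ")

  ## map test labels onto the training dichotomy: the training positive
  ## class stands for "movement", so any non-reference test condition maps
  ## to it (actual -> attempted transfer)
  lam <- select_lambda(trX, train_labels, derive_seed(seed, "transfer-select"))
  model <- fit_rllr(trX, train_labels, as.numeric(lam))
  score <- predict(model, teX, type = "decision")
  te_lab <- as.factor(test_labels)
  if (nlevels(te_lab) != 2L) stop_invalid("test labels must have 2 classes")
  ## align classes: the shared level (typically 'none') is the negative one
  shared <- intersect(model$levels, levels(te_lab))
  neg <- if ("none" %in% shared) "none" else if (length(shared)) shared[1] else levels(te_lab)[1]
  truth_pos <- te_lab != neg
  model_neg_is_first <- model$levels[1] == neg
  pred_pos <- if (model_neg_is_first) score > 0 else score < 0
  list(accuracy = mean(pred_pos == truth_pos),
       decision_values = if (model_neg_is_first) score else -score,
       predictions = pred_pos,
       lambda = as.numeric(lam),
       model = model)
}
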