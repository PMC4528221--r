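## Accuracy confidence intervals: exact binomial (Clopper-Pearson) per
## subject, t-based CI for the group mean, and a permutation check of the
## 50% chance level.

#' Binomial confidence interval for a classification accuracy
#'
#' Clopper-Pearson exact interval from beta quantiles by default; a
#' normal-approximation option (`p +/- z * sqrt(p(1-p)/n)`) is also
#' provided. All quantities in percent.
#'
#' @param correct Number of correctly classified trials.
#' @param n Total trials.
#' @param level Confidence level (default 0.95).
#' @param method "clopper_pearson" (default) or "normal".
#' @return An `accuracy_ci` list: accuracy, lower, upper (percent), n,
#'   method.
#' @export
binomial_ci <- function(correct, n, level = 0.95,
                        method = c("clopper_pearson", "normal")) {
  method <- match.arg(method)
  check_number(correct, "correct", nonneg = TRUE)
  check_number(n, "n", positive = TRUE)
  if (correct > n) stop_invalid("`correct` cannot exceed `n`")
  p <- correct / n
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (correct == 0) 0 else stats::qbeta(alpha / 2, correct, n - correct + 1)
    upper <- if (correct == n) 1 else stats::qbeta(1 - alpha / 2, correct + 1, n - correct)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lower <- max(0, p - half)
    upper <- min(1, p + half)
  }
  structure(list(accuracy = 100 * p, lower = 100 * lower, upper = 100 * upper,
                 n = n, level = level, method = method),
            class = "accuracy_ci")
}

#' @export
print.accuracy_ci <- function(x, ...) {
  cat(sprintf("%.0f (%.0f-%.0f)%% [%s, n = %d]\n",
              round_half_up(x$accuracy), round_half_up(x$lower),
              round_half_up(x$upper), x$method, x$n))
  invisible(x)
}

#' Confidence interval for a group-mean accuracy
#'
#' Standard t interval: `mean +/- t(1 - alpha/2, n-1) * sd / sqrt(n)`.
#' Inputs and outputs in percent. Bounds are not clamped (a display layer
#' may clip to [0, 100]).
#'
#' @param accuracies Per-subject accuracies in percent (>= 2 values).
#' @param level Confidence level (default 0.95).
#' @return A `group_ci` list: mean, lower, upper, n_subjects.
#' @export
group_mean_ci <- function(accuracies, level = 0.95) {
  n <- length(accuracies)
  if (n < 2) stop_invalid("need at least 2 accuracies for a group CI")
  m <- mean(accuracies)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(accuracies) / sqrt(n)
  structure(list(mean = m, lower = m - half, upper = m + half,
                 n_subjects = n, level = level),
            class = "group_ci")
}

#' @export
print.group_ci <- function(x, ...) {
  cat(sprintf("%.0f (%.0f-%.0f)%% [group mean, n = %d]\n",
              round_half_up(x$mean),
              round_half_up(max(0, x$lower)), round_half_up(min(100, x$upper)),
              x$n_subjects))
  invisible(x)
}

#' Permutation verification of the chance level
#'
#' Shuffles labels `n_perm` times, recomputes the cross-validated accuracy
#' for each shuffle, and reports the empirical quantile of the unpermuted
#' accuracy within the permutation distribution. Under a balanced two-class
#' design the distribution centers on 50%.
#'
#' @param features `feature_matrix` or matrix.
#' @param labels Binary labels.
#' @param n_perm Number of permutations (>= 20).
#' @param seed Integer seed (shuffle sequence and CV folds).
#' @param k CV folds (default 10).
#' @param selection Lambda-selection mode passed to [crossval_accuracy()].
#' @return List: `observed` accuracy, `perm_accuracies`, `quantile` (rank of
#'   observed within permutations), `p_value` (upper-tail, +1 correction).
#' @export
permutation_chance <- function(features, labels, n_perm, seed = 1, k = 10,
                               selection = "nested") {
  if (n_perm < 20) stop_invalid("`n_perm` must be >= 20")
  if (inherits(features, "feature_matrix")) features <- features$values
  lab <- as.factor(labels)
  observed <- crossval_accuracy(features, lab, k = k,
                                seed = derive_seed(seed, "observed"),
                                selection = selection)$overall_accuracy
  perm <- vapply(seq_len(n_perm), function(i) {
    lab_i <- with_seed(derive_seed(seed, paste0("perm", i)),
                       lab[sample.int(length(lab))])
    crossval_accuracy(features, lab_i, k = k,
                      seed = derive_seed(seed, paste0("cv", i)),
                      selection = selection)$overall_accuracy
  }, numeric(1))
  list(observed = observed,
       perm_accuracies = perm,
       quantile = mean(perm < observed),
       p_value = (sum(perm >= observed) + 1) / (n_perm + 1))
}
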