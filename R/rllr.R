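## Quadratically regularized linear logistic regression (rLLR): minimize the
## logistic negative log-likelihood plus lambda * ||w||^2 (bias unpenalized).
## Features are standardized internally (parameters stored with the model).
## Optimization: L-BFGS warm pass, then Newton polishing to drive the
## gradient below tolerance. Regularization strength is grid-searched over
## [.001 .01 .1 1 10 100] times the total data variance by inner ten-fold
## cross-validation.

log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

rllr_objective <- function(par, X, y, lambda) {
  eta <- drop(X %*% par[-1]) + par[1]
  sum(log1pexp(eta) - y * eta) + lambda * sum(par[-1]^2)
}

rllr_gradient <- function(par, X, y, lambda) {
  eta <- drop(X %*% par[-1]) + par[1]
  r <- stats::plogis(eta) - y
  c(sum(r), drop(crossprod(X, r)) + 2 * lambda * par[-1])
}

#' Fit a regularized linear logistic regression classifier
#'
#' Binary classifier minimizing the logistic negative log-likelihood plus
#' `lambda * ||weights||^2` (bias unpenalized) to a gradient max-norm below
#' `tol`. The decision value is the linear score; the predicted class is its
#' sign. Features are standardized internally; standardization parameters
#' are stored and reused at prediction time.
#'
#' @param features A `feature_matrix` or a plain trials x features matrix.
#' @param labels Binary labels (factor/character/logical); the second factor
#'   level is the positive class.
#' @param lambda Regularization strength, >= 0.
#' @param tol Gradient max-norm tolerance (default 1e-6).
#' @param init Optional warm-start parameter vector c(bias, weights).
#' @return An `rllr` model: weights, bias, lambda, standardization
#'   parameters, class levels, and the training feature metadata.
#' @export
fit_rllr <- function(features, labels, lambda, tol = 1e-6, init = NULL) {
  meta <- NULL
  if (inherits(features, "feature_matrix")) {
    meta <- features$meta
    features <- features$values
  }
  if (!all(is.finite(features))) stop_invalid("features contain non-finite values")
  check_number(lambda, "lambda", nonneg = TRUE)
  lab <- as.factor(labels)
  if (nlevels(lab) != 2L) {
    stop_invalid(sprintf("need exactly 2 classes in `labels` (got %d)", nlevels(lab)))
  }
  y <- as.numeric(lab) - 1

  mu <- colMeans(features)
  sdev <- apply(features, 2, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdev, "/")

  p <- ncol(X)
  par0 <- if (is.null(init)) numeric(p + 1) else init
  opt <- stats::optim(par0, rllr_objective, rllr_gradient,
                      X = X, y = y, lambda = lambda,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 10))
  par <- opt$par
  ## Newton polish (exact Hessian) until the gradient tolerance is met; on
  ## separable data with lambda ~ 0 the optimum is at infinity, so cap steps
  for (it in seq_len(25)) {
    g <- rllr_gradient(par, X, y, lambda)
    if (max(abs(g)) < tol) break
    eta <- drop(X %*% par[-1]) + par[1]
    wgt <- stats::plogis(eta) * (1 - stats::plogis(eta))
    wgt <- pmax(wgt, 1e-10)
    Xa <- cbind(1, X)
    H <- crossprod(Xa, Xa * wgt) + diag(c(0, rep(2 * lambda, p)))
    step <- tryCatch(solve(H, g), error = function(e) g / max(1, max(abs(g))))
    f0 <- rllr_objective(par, X, y, lambda)
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      if (rllr_objective(cand, X, y, lambda) <= f0 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    par <- par - alpha * step
  }
  structure(list(bias = par[1], weights = par[-1], lambda = lambda,
                 center = mu, scale = sdev, levels = levels(lab),
                 feature_meta = meta,
                 grad_norm = max(abs(rllr_gradient(par, X, y, lambda)))),
            class = "rllr")
}

#' Decision values and class predictions from an rLLR model
#'
#' @param object An `rllr` model.
#' @param newdata A `feature_matrix` or matrix with the training feature
#'   layout; training standardization is reused.
#' @param type "class" (default) or "decision" (linear score; positive =
#'   second training level).
#' @param ... Unused.
#' @return Factor of predicted classes, or numeric decision values.
#' @export
predict.rllr <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$values
  X <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  score <- drop(X %*% object$weights) + object$bias
  if (type == "decision") return(score)
  factor(object$levels[(score > 0) + 1], levels = object$levels)
}

#' @export
print.rllr <- function(x, ...) {
  cat(sprintf("<rllr> %d features, lambda = %.4g, |grad| = %.2g, classes %s/%s\n",
              length(x$weights), x$lambda, x$grad_norm, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Serialize an rLLR model to JSON
#' @param model An `rllr`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_rllr_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The regularization grid: multipliers of the total data variance
#' @return Numeric vector of the 6 grid multipliers.
#' @export
lambda_grid_multipliers <- function() c(0.001, 0.01, 0.1, 1, 10, 100)

#' Grid-search the regularization strength
#'
#' Candidate strengths are `lambda_grid_multipliers()` times the total data
#' variance (sum over feature columns of their variance across trials).
#' Each candidate is scored by stratified `k_inner`-fold cross-validated
#' accuracy; the maximizer is returned, ties broken toward the larger
#' strength (simpler model).
#'
#' @param features `feature_matrix` or matrix.
#' @param labels Binary labels.
#' @param seed Integer seed for the inner fold split.
#' @param k_inner Inner folds (default 10).
#' @return Selected lambda, with the candidate grid and per-candidate
#'   accuracies in attributes.
#' @export
select_lambda <- function(features, labels, seed, k_inner = 10) {
  if (inherits(features, "feature_matrix")) features <- features$values
  if (nrow(features) < 20) stop_invalid("need at least 20 trials to select lambda")
  totvar <- sum(apply(features, 2, stats::var))
  candidates <- lambda_grid_multipliers() * totvar
  lab <- as.factor(labels)
  folds <- stratified_folds(lab, k_inner, seed)
  acc <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    correct <- 0L
    for (f in seq_len(k_inner)) {
      tr <- folds != f
      fit <- fit_rllr(features[tr, , drop = FALSE], lab[tr], candidates[j])
      pred <- predict(fit, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == lab[!tr])
    }
    acc[j] <- correct / length(lab)
  }
  best <- max(which(acc == max(acc)))        # tie -> larger lambda
  structure(candidates[best],
            multiplier = lambda_grid_multipliers()[best],
            candidates = candidates, accuracies = acc)
}
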