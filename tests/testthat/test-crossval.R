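test_that("stratified folds balance classes within one trial", {
  y <- factor(rep(c("none", "move"), each = 81))
  folds <- stratified_folds(y, 10, seed = 3)
  sizes <- table(folds)
  expect_true(all(sizes %in% c(16, 17)))
  per_class <- table(folds, y)
  expect_true(all(abs(per_class[, 1] - per_class[, 2]) <= 1))
  # reproducible and seed-sensitive
  expect_identical(folds, stratified_folds(y, 10, seed = 3))
  expect_false(identical(folds, stratified_folds(y, 10, seed = 4)))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 100)), 10, 1), "smaller k")
})

test_that("held-out predictions come from models that never saw the fold", {
  gf <- gaussian_features(30, 5, shift = 1, seed = 7)
  cv <- crossval_accuracy(gf$x, gf$y, k = 5, seed = 2, selection = "flat")
  ## recompute fold 1 by hand with the same flat lambda
  lam <- unique(cv$chosen_lambda)
  expect_length(lam, 1)
  tr <- cv$folds != 1
  fit <- fit_rllr(gf$x[tr, ], gf$y[tr], lam)
  expect_equal(as.character(predict(fit, gf$x[!tr, , drop = FALSE])),
               as.character(cv$predictions[!tr]))
  ## bookkeeping: every trial is held out exactly once
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(cv$overall_accuracy, mean(cv$predictions == gf$y))
})

test_that("perfectly separable features give perfect CV accuracy", {
  x <- matrix(c(rnorm(40, -4), rnorm(40, 4)), ncol = 1)
  y <- rep(c("none", "move"), each = 40)
  cv <- crossval_accuracy(x, y, k = 10, seed = 1)
  expect_equal(cv$overall_accuracy, 1)
  expect_equal(cv$fold_accuracies, rep(1, 10))
})

test_that("label-independent features stay at chance", {
  accs <- vapply(1:20, function(s) {
    gf <- gaussian_features(81, 4, shift = 0, seed = 200 + s)
    crossval_accuracy(gf$x, gf$y, k = 10, seed = s)$overall_accuracy
  }, numeric(1))
  expect_gte(sum(accs >= 0.40 & accs <= 0.60), 18)
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("accuracy is invariant to feature column permutation", {
  gf <- gaussian_features(30, 6, shift = 0.8, seed = 8)
  cv1 <- crossval_accuracy(gf$x, gf$y, k = 5, seed = 9)
  perm <- c(4, 2, 6, 1, 5, 3)
  cv2 <- crossval_accuracy(gf$x[, perm], gf$y, k = 5, seed = 9)
  expect_equal(cv2$overall_accuracy, cv1$overall_accuracy)
  expect_equal(cv2$predictions, cv1$predictions)
})

test_that("self-transfer reproduces the training accuracy", {
  gf <- gaussian_features(30, 5, shift = 1, seed = 10)
  res <- transfer_accuracy(gf$x, gf$y, gf$x, gf$y, seed = 1)
  fit <- fit_rllr(gf$x, gf$y, res$lambda)
  expect_equal(res$accuracy, mean(predict(fit, gf$x) == gf$y))
})

test_that("a classifier trained on noise transfers at chance", {
  accs <- vapply(1:20, function(s) {
    tr <- gaussian_features(40, 4, shift = 0, seed = 300 + s)
    te <- gaussian_features(40, 4, shift = 2, seed = 400 + s)
    transfer_accuracy(tr$x, tr$y, te$x, te$y, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.07)
})

test_that("mismatched feature metadata is rejected", {
  sess <- memoize("p2_default", tiny_session(2, seed = 11))
  ep <- extract_epochs(sess$rec, sess$plan)
  f9 <- extract_features(ep, channels = motor_channels())
  f3 <- extract_features(ep, channels = c("C3", "Cz", "C4"))
  expect_error(transfer_accuracy(f9, f9$labels, f3, f3$labels), "differ")
})
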