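test_that("the fitted optimum zeroes the penalized-loss gradient", {
  gf <- gaussian_features(30, 8, shift = 0.8, seed = 1)
  for (lambda in c(0.5, 5)) {
    fit <- fit_rllr(gf$x, gf$y, lambda)
    X <- sweep(sweep(gf$x, 2, fit$center), 2, fit$scale, "/")
    g <- numeric_rllr_gradient(c(fit$bias, fit$weights), X,
                               as.numeric(gf$y) - 1, lambda)
    expect_lt(max(abs(g)), 1e-5)
  }
})

test_that("separable clusters are fit perfectly at small lambda", {
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1)
  y <- rep(c("none", "move"), each = 20)
  fit <- fit_rllr(x, y, 1e-6)
  expect_equal(mean(predict(fit, x) == y), 1)
})

test_that("infinite shrinkage collapses the weights", {
  gf <- gaussian_features(40, 6, shift = 1, seed = 2)
  fit <- fit_rllr(gf$x, gf$y, 1e9 * sum(apply(gf$x, 2, var)))
  expect_lt(sqrt(sum(fit$weights^2)), 1e-3)
})

test_that("the weight norm shrinks monotonically in lambda", {
  gf <- gaussian_features(40, 10, shift = 0.6, seed = 3)
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    sqrt(sum(fit_rllr(gf$x, gf$y, l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("at vanishing penalty the fit agrees with glm", {
  gf <- gaussian_features(60, 3, shift = 0.7, seed = 4)
  fit <- fit_rllr(gf$x, gf$y, 1e-10)
  X <- sweep(sweep(gf$x, 2, fit$center), 2, fit$scale, "/")
  ref <- glm((as.numeric(gf$y) - 1) ~ X, family = binomial())
  expect_equal(unname(c(fit$bias, fit$weights)), unname(coef(ref)),
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(fit_rllr(x, rep("a", 10), 1), "2 classes")
  x2 <- x; x2[1] <- NA
  expect_error(fit_rllr(x2, rep(c("a", "b"), 5), 1), "non-finite")
  expect_error(fit_rllr(x, rep(c("a", "b"), 5), -1), "lambda")
})

test_that("decision values are the linear score, classes its sign", {
  gf <- gaussian_features(25, 4, shift = 1, seed = 5)
  fit <- fit_rllr(gf$x, gf$y, 1)
  sc <- predict(fit, gf$x, type = "decision")
  cl <- predict(fit, gf$x)
  expect_equal(cl == levels(gf$y)[2], sc > 0, ignore_attr = TRUE)
})

test_that("the lambda grid has 6 candidates tied to the total variance", {
  gf <- gaussian_features(30, 5, shift = 0.5, seed = 6)
  lam <- select_lambda(gf$x, gf$y, seed = 1)
  cand <- attr(lam, "candidates")
  expect_equal(length(cand), 6)
  totvar <- sum(apply(gf$x, 2, var))
  expect_equal(cand, c(0.001, 0.01, 0.1, 1, 10, 100) * totvar)
  expect_true(as.numeric(lam) %in% cand)
})

test_that("zero-variance features select the largest (zero) candidate", {
  x <- matrix(1, 40, 3)
  y <- rep(c("a", "b"), 20)
  lam <- select_lambda(x, y, seed = 1)
  expect_equal(as.numeric(lam), 0)
  expect_equal(attr(lam, "multiplier"), 100)  # tie broken to strongest
})

test_that("separable data prefers weak regularization in most seeds", {
  ## separability here lives in a noise-cancelling direction (f1 - f2), not
  ## in the class-mean difference, so heavy shrinkage genuinely loses
  hits <- vapply(1:10, function(s) {
    brainswitch:::with_seed(500 + s, {
      n <- 25
      z <- rnorm(2 * n)
      sgn <- rep(c(-1, 1), each = n)
      x <- cbind(sgn * 0.8 + z, z, matrix(rnorm(2 * n * 2), 2 * n))
      y <- factor(rep(c("none", "move"), each = n), levels = c("none", "move"))
      attr(select_lambda(x, y, seed = s), "multiplier") <= 1
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the returned lambda maximizes inner-CV accuracy, ties to stronger", {
  gf <- gaussian_features(25, 4, shift = 3, seed = 42)
  lam <- select_lambda(gf$x, gf$y, seed = 2)
  acc <- attr(lam, "accuracies")
  cand <- attr(lam, "candidates")
  expect_equal(as.numeric(lam), max(cand[acc == max(acc)]))
})
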