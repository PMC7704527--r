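test_that("noiseless planted coefficients are recovered exactly", {
  X <- random_matrix(10, 2, seed = 2)
  y <- 2 * X[, 1] - 3 * X[, 2] + 1
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$model$coefficients), c(2, -3), tolerance = 1e-8)
  expect_equal(fit$model$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$stats$sse, 0, tolerance = 1e-14)
})

test_that("constant response gives zero slopes and mean intercept", {
  X <- random_matrix(8, 2, seed = 4)
  y <- rep(2.5, 8)
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$model$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$model$intercept, 2.5, tolerance = 1e-10)
})

test_that("solution equals an independent normal-equations oracle", {
  set.seed(31)
  X <- random_matrix(12, 3, seed = 31)
  y <- rnorm(12)
  fit <- fit_ols(X, y)
  A <- cbind(1, X)
  beta_oracle <- solve(t(A) %*% A, t(A) %*% y)  # normal equations
  expect_equal(fit$model$intercept, beta_oracle[1], tolerance = 1e-10)
  expect_equal(unname(fit$model$coefficients), unname(beta_oracle[-1]),
               tolerance = 1e-10)
  # SEE definition: sqrt(SSE / (N - P - 1))
  res <- y - A %*% beta_oracle
  expect_equal(fit$stats$see, sqrt(sum(res^2) / (12 - 3 - 1)),
               tolerance = 1e-10)
})

test_that("residuals are orthogonal to the design and sum to zero", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- random_matrix(15, 4, seed = seed + 100)
    y <- rnorm(15)
    fit <- fit_ols(X, y)
    res <- y - predict(fit$model, X)
    expect_lt(abs(sum(res)), 1e-8)
    expect_lt(max(abs(t(X) %*% res)) / max(abs(y)), 1e-6)
  }
})

test_that("rank-deficient designs are refused with the offending column", {
  X <- random_matrix(10, 2, seed = 8)
  X <- cbind(X, dupe = X[, 1])
  y <- rnorm(10)
  expect_error(fit_ols(X, y), "dupe")
})

test_that("activity vectors align by compound name, not position", {
  X <- random_matrix(10, 2, seed = 12)
  y <- 0.5 * X[, 1] + rnorm(10, sd = 0.01)
  names(y) <- rownames(X)
  shuffled <- y[rev(names(y))]
  f1 <- fit_ols(X, y)
  f2 <- fit_ols(X, shuffled)
  expect_equal(f1$model$coefficients, f2$model$coefficients)
})

test_that("lack-of-fit matches direct arithmetic and is monotone in SSE", {
  expect_equal(lof(0, m = 27, c = 4, d = 0.5), 0)
  # (0.9447/27) / (1 - 6.5/27)^2
  expect_equal(lof(0.9447, m = 27, c = 4, p = 5, d = 0.5),
               (0.9447 / 27) / (1 - 6.5 / 27)^2, tolerance = 1e-12)
  expect_equal(lof(0.9447, m = 27, c = 4, p = 5, d = 0.5), 0.06070,
               tolerance = 1e-4)
  expect_equal(lof(2 * 0.9447, m = 27, c = 4, p = 5, d = 0.5),
               2 * lof(0.9447, m = 27, c = 4, p = 5, d = 0.5))
  expect_error(lof(1, m = 10, c = 8, p = 9, d = 1), "over-parameterized")
})

test_that("lack-of-fit ignores descriptor order within a model", {
  X <- random_matrix(20, 4, seed = 44)
  y <- rnorm(20)
  f1 <- fit_ols(X, y, support = c("d01", "d03", "d04"))
  f2 <- fit_ols(X, y, support = c("d04", "d01", "d03"))
  expect_equal(lof(f1$stats$sse, 20, 3), lof(f2$stats$sse, 20, 3))
})
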