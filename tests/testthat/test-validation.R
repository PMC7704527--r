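test_that("R2 matches hand arithmetic and the published external table", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4), ref_mean = 2), 0.5)
  t3 <- table3_fixture()
  expect_equal(r_squared(t3$pic50_obs, t3$pic50_pred_printed,
                         ref_mean = 4.5364),
               0.5357, tolerance = 1e-3)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero total sum of squares")
})

test_that("adjusted R2 uses the standard small-sample correction", {
  expect_equal(adjusted_r2(1, 27, 4), 1)
  expect_equal(adjusted_r2(0.6981, 27, 4), 0.6433, tolerance = 1e-3)
  expect_equal(adjusted_r2(0.5, 12, 4), 1 - 0.5 * 11 / 7, tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 5, 4), "n > p")
})

test_that("leave-one-out Q2 equals the literal refit oracle", {
  set.seed(61)
  for (n in c(8, 15, 30)) {
    X <- random_matrix(n, 3, seed = n)
    y <- 0.7 * X[, 1] - 0.3 * X[, 2] + rnorm(n, sd = 0.3)
    got <- q2_loo(X, y, support = c("d01", "d02"))
    # oracle: n literal lm() refits
    preds <- vapply(seq_len(n), function(i) {
      df <- data.frame(y = y[-i], X[-i, c("d01", "d02")])
      fit <- lm(y ~ d01 + d02, data = df)
      predict(fit, newdata = as.data.frame(X[i, , drop = FALSE]))
    }, numeric(1))
    q2_oracle <- 1 - sum((preds - y)^2) / sum((y - mean(y))^2)
    expect_equal(got$q2, q2_oracle, tolerance = 1e-10)
    expect_equal(unname(got$loo_predictions), preds, tolerance = 1e-10)
  }
})

test_that("Q2 is 1 for exact linear data and <= R2 on noisy fits", {
  X <- random_matrix(12, 2, seed = 71)
  y_exact <- 1 + X[, 1] - 2 * X[, 2]
  expect_equal(q2_loo(X, y_exact)$q2, 1, tolerance = 1e-9)
  expect_error(q2_loo(X, rep(1, 12)), "constant")
  for (seed in 1:5) {
    set.seed(seed)
    y <- y_exact + rnorm(12, sd = 0.5)
    r2 <- fit_ols(X, y)$stats$r2
    expect_lte(q2_loo(X, y)$q2, r2)
  }
})

test_that("external validation reproduces the published sums of squares", {
  t3 <- table3_fixture()
  ext <- external_r2pred(t3$pic50_obs, t3$pic50_pred_printed, 4.5364)
  expect_equal(ext$ss_res, 0.713008, tolerance = 2e-4)
  expect_equal(ext$ss_tot, 1.535707, tolerance = 2e-4)
  expect_equal(ext$r2_pred, 0.5357, tolerance = 1e-3)
  expect_equal(ext$r2_pred, 1 - ext$ss_res / ext$ss_tot)

  obs <- c(4, 5, 6)
  expect_equal(external_r2pred(obs, rep(5, 3), 5)$r2_pred, 0)
  expect_equal(external_r2pred(obs, obs, 5)$r2_pred, 1)
  expect_error(external_r2pred(rep(5, 3), obs, 5), "zero total")
})

test_that("mean effects are normalized signed contributions", {
  m <- qsar_model(c("A", "B"), c(2, -1), 0)
  D <- matrix(c(1, 2, 0, 1, 1, 2), 3, 2, dimnames = list(NULL, c("A", "B")))
  # column sums (3, 4): ME = (6, -4)/2 = (3, -2)
  expect_equal(unname(mean_effect(m, D)), c(3, -2))

  single <- qsar_model("A", 5, 1)
  expect_equal(unname(mean_effect(single, D)), 1)

  set.seed(81)
  for (i in 1:5) {
    D <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, LETTERS[1:4]))
    mm <- qsar_model(LETTERS[1:4], rnorm(4), rnorm(1))
    me <- mean_effect(mm, D)
    expect_equal(sum(me), 1, tolerance = 1e-9)
    # permuting descriptor order permutes the mean effects identically
    perm <- c(3, 1, 4, 2)
    mp <- qsar_model(LETTERS[perm], mm$coefficients[perm], mm$intercept)
    expect_equal(mean_effect(mp, D), me[perm])
  }
})

test_that("VIF matches the two-column closed form and flags collinearity", {
  # exact sample correlation 0.8 by orthonormal construction
  x1 <- c(1, -1, 0, 0)
  z <- c(0, 0, 1, -1)
  D <- cbind(A = x1, B = 0.8 * x1 + 0.6 * z, C = z)
  expect_equal(unname(vif(D, c("A", "B"))), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-10)
  expect_equal(unname(vif(D, c("A", "C"))), c(1, 1), tolerance = 1e-10)

  dup <- cbind(D[, c("A", "C")], A2 = D[, "A"])
  expect_equal(unname(vif(dup, c("A", "A2"))), c(Inf, Inf))

  set.seed(91)
  for (i in 1:5) {
    R <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, LETTERS[1:4]))
    expect_true(all(vif(R) >= 1 - 1e-12))
  }
})

test_that("correlation matrix matches the covariance-formula oracle", {
  set.seed(101)
  D <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  cm <- correlation_matrix(D)
  expect_equal(diag(cm), setNames(rep(1, 3), c("A", "B", "C")))
  expect_equal(cm, t(cm))
  for (i in 1:3) for (j in 1:3) {
    a <- D[, i]; b <- D[, j]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cm[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(correlation_matrix(cbind(x = D[, 1], negx = -D[, 1]))[1, 2], -1)
  expect_error(correlation_matrix(cbind(A = D[, 1], B = rep(1, 20))),
               "zero-variance")
})

test_that("recommended-threshold verdicts follow the published table", {
  # published Model 1 values: all evaluated criteria pass
  g <- evaluate_against_criteria(r2 = 0.6981, q2 = 0.5460,
                                 r2_ext = 0.5357, n_test = 12)
  expect_true(attr(g, "overall"))
  expect_true(all(g$pass[!is.na(g$pass)]))
  expect_true(is.na(g$pass[g$criterion == "P (95%)"]))

  gap <- evaluate_against_criteria(0.9, 0.5, 0.6, 12)
  expect_false(gap$pass[gap$criterion == "R2 - Q2"])
  expect_false(attr(gap, "overall"))

  small <- evaluate_against_criteria(0.7, 0.6, 0.6, 4)
  expect_false(small$pass[small$criterion == "N test"])
})
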