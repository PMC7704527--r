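test_that("search space of size one returns the full support", {
  X <- random_matrix(12, 3, seed = 7)
  y <- rnorm(12)
  cfg <- gfa_config(population_size = 4, generations = 2,
                    model_size_min = 3, model_size_max = 3, seed = 1)
  res <- gfa(X, y, config = cfg)
  expect_equal(sort(res$ranked_models[[1]]$model$descriptors),
               sort(colnames(X)))
})

test_that("same seed gives an identical run; different seed may differ", {
  ds <- make_benchmark("easy", seed = 5)
  cfg <- gfa_config(population_size = 30, generations = 20, seed = 42)
  r1 <- gfa(ds$descriptors, ds$activities, config = cfg, top_k = 5)
  r2 <- gfa(ds$descriptors, ds$activities, config = cfg, top_k = 5)
  expect_equal(lapply(r1$ranked_models, function(m) m$model$descriptors),
               lapply(r2$ranked_models, function(m) m$model$descriptors))
  expect_equal(vapply(r1$ranked_models, `[[`, numeric(1), "lof"),
               vapply(r2$ranked_models, `[[`, numeric(1), "lof"))
})

test_that("best-so-far lack-of-fit never increases across generations", {
  ds <- make_benchmark("easy", seed = 3)
  cfg <- gfa_config(population_size = 20, generations = 30, seed = 9)
  res <- gfa(ds$descriptors, ds$activities, config = cfg)
  expect_true(all(diff(res$best_lof_history) <= 0))
})

test_that("with full size-k coverage the winner matches brute force", {
  set.seed(55)
  X <- random_matrix(20, 8, seed = 55)
  y <- 0.8 * X[, 2] - 0.6 * X[, 5] + rnorm(20, sd = 0.2)
  k <- 2
  combos <- utils::combn(8, k, simplify = FALSE)
  # independent brute-force enumeration of every size-k equation
  brute <- vapply(combos, function(s) {
    f <- fit_ols(X, y, support = colnames(X)[s])
    lof(f$stats$sse, m = 20, c = k, p = k + 1, d = 2)
  }, numeric(1))
  best_brute <- combos[[which.min(brute)]]

  cfg <- gfa_config(population_size = length(combos), generations = 3,
                    model_size_min = k, model_size_max = k,
                    mutation_prob = 0, smoothing_d = 2, seed = 1)
  res <- gfa(X, y, config = cfg, initial_population = combos)
  expect_equal(sort(res$ranked_models[[1]]$model$descriptors),
               sort(colnames(X)[best_brute]))
  expect_equal(res$ranked_models[[1]]$lof, min(brute), tolerance = 1e-12)
})

test_that("a planted four-descriptor model is recovered from one seed", {
  ds <- make_benchmark("easy", seed = 1)
  res <- gfa(ds$descriptors, ds$activities, config = gfa_config(seed = 1))
  expect_equal(sort(res$ranked_models[[1]]$model$descriptors),
               sort(ds$truth$support_names))
})

test_that("ranking is ascending in LOF with stable ties", {
  cands <- list(list(lof = 0.3, tag = "a"), list(lof = 0.1, tag = "b"),
                list(lof = 0.2, tag = "c"))
  expect_equal(vapply(rank_models(cands), `[[`, character(1), "tag"),
               c("b", "c", "a"))
  ties <- list(list(lof = 0.2, tag = "first"), list(lof = 0.2, tag = "second"))
  expect_equal(vapply(rank_models(ties), `[[`, character(1), "tag"),
               c("first", "second"))
  set.seed(17)
  lofs <- runif(25)
  cands <- lapply(lofs, function(l) list(lof = l))
  expect_equal(vapply(rank_models(cands), `[[`, numeric(1), "lof"),
               sort(lofs))
})

test_that("infeasible configurations are refused", {
  X <- random_matrix(10, 3, seed = 2)
  y <- rnorm(10)
  expect_error(gfa(X, y, config = gfa_config(model_size_max = 5)),
               "exceeds descriptor count")
  expect_error(gfa(random_matrix(5, 4, seed = 2), rnorm(5),
                   config = gfa_config(model_size_min = 4, model_size_max = 4)),
               "too few compounds")
})
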