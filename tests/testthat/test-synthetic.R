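test_that("the same seed regenerates the dataset bit-identically", {
  spec <- synthetic_spec(20, 10, support = c(1, 4), seed = 7,
                         true_coefficients = c(1, -0.5),
                         descriptor_correlation = 0.3, n_constant = 1,
                         n_duplicate = 1)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$descriptors, d2$descriptors)
  expect_identical(d1$activities, d2$activities)
  d3 <- generate_dataset(synthetic_spec(20, 10, support = c(1, 4), seed = 8,
                                        true_coefficients = c(1, -0.5)))
  expect_false(identical(d1$activities, d3$activities))
})

test_that("noiseless data lets OLS recover the planted coefficients", {
  spec <- synthetic_spec(25, 12, support = c(2, 5, 9), noise_sd = 0,
                         true_coefficients = c(0.8, -0.4, 0.3),
                         intercept = 5, seed = 3)
  ds <- generate_dataset(spec)
  fit <- fit_ols(ds$descriptors, ds$activities,
                 support = ds$truth$support_names)
  expect_equal(unname(fit$model$coefficients), spec$true_coefficients,
               tolerance = 1e-8)
  expect_equal(fit$model$intercept, 5, tolerance = 1e-8)
})

test_that("block correlation approaches the requested exchangeable r", {
  spec <- synthetic_spec(4000, 10, support = 1, true_coefficients = 1,
                         descriptor_correlation = 0.6, block_size = 5,
                         seed = 11)
  ds <- generate_dataset(spec)
  cm <- cor(ds$descriptors[, 1:5])
  off <- cm[upper.tri(cm)]
  expect_equal(mean(off), 0.6, tolerance = 0.05)
  # across blocks: uncorrelated
  expect_lt(abs(cor(ds$descriptors[, 1], ds$descriptors[, 6])), 0.1)
})

test_that("OLS estimates land within 3 standard errors of truth", {
  # sampling-theory check: ~99% coverage expected at 3 SE
  hits <- 0
  for (seed in 1:200) {
    spec <- synthetic_spec(200, 2, support = c(1, 2),
                           true_coefficients = c(2, -1), noise_sd = 0.1,
                           seed = seed)
    ds <- generate_dataset(spec)
    df <- data.frame(y = as.numeric(ds$activities), ds$descriptors)
    fit <- summary(lm(y ~ D001 + D002, data = df))$coefficients
    ok <- abs(fit["D001", "Estimate"] - 2) < 3 * fit["D001", "Std. Error"] &&
      abs(fit["D002", "Estimate"] + 1) < 3 * fit["D002", "Std. Error"]
    hits <- hits + ok
  }
  expect_gte(hits, 0.99 * 200 - 3)  # binomial slack at n = 200
})

test_that("benchmark presets have the documented shapes", {
  easy <- make_benchmark("easy", seed = 1)
  expect_equal(dim(easy$descriptors), c(40, 30))
  expect_length(easy$truth$support_names, 4)

  pl <- make_benchmark("paper_like", seed = 1)
  expect_equal(nrow(pl$descriptors), 39)
  expect_equal(ncol(pl$descriptors), 1000)
  expect_length(pl$truth$constant_names, 20)
  expect_length(pl$truth$duplicate_names, 20)
})

test_that("injected pathologies are caught by the matching stage", {
  ds <- make_benchmark("easy", seed = 2)
  ds <- inject_pathologies(ds, c("constant", "duplicate", "missing"))

  expect_error(inject_pathologies(ds, "gremlins"), "unknown pathology")

  # constant and duplicate columns fall to pretreatment
  clean <- ds$descriptors
  clean[is.na(clean)] <- 0  # patch the missing cell so pretreat can run
  out <- pretreat(clean)
  expect_true("PATH_CONST" %in% out$report$removed_constant)
  expect_true("PATH_DUP" %in% out$report$removed_correlated$dropped)

  # the missing cell makes the CSV round-trip fail with coordinates
  paths <- write_synthetic_dataset(ds, tempfile("synth"))
  err <- tryCatch(read_descriptor_matrix(paths["descriptors"]),
                  error = conditionMessage)
  expect_match(err, ds$truth$missing_cell["row"])
  expect_match(err, ds$truth$missing_cell["column"])
})

test_that("invalid specs are refused", {
  expect_error(synthetic_spec(10, 5, support = 6, true_coefficients = 1),
               "support")
  expect_error(synthetic_spec(10, 5, support = 1, true_coefficients = c(1, 2)),
               "one true coefficient")
  expect_error(synthetic_spec(10, 5, support = 1, true_coefficients = 1,
                              noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(10, 5, support = 1, true_coefficients = 1,
                              descriptor_correlation = 1), "correlation")
})

test_that("correlated decoys reduce but do not abolish support recovery", {
  recovered <- 0
  for (seed in 1:10) {
    ds <- make_benchmark("hard", seed = seed)
    res <- gfa(ds$descriptors, ds$activities,
               config = gfa_config(seed = seed), top_k = 1)
    top <- sort(res$ranked_models[[1]]$model$descriptors)
    recovered <- recovered + identical(top, sort(ds$truth$support_names))
  }
  expect_gte(recovered, 3)
})

test_that("split-pretreat-search-validate recovers a strong model on easy data", {
  good <- 0
  for (seed in 1:10) {
    ds <- make_benchmark("easy", seed = seed)
    rep <- run_full_study(ds$descriptors, ds$activities,
                          gfa_config = gfa_config(seed = seed))
    good <- good + (rep$validation$internal$r2 >= 0.9 &&
                    rep$validation$internal$q2_loo >= 0.8)
  }
  expect_gte(good, 8)
})
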