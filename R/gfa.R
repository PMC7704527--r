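#' Fit an ordinary least-squares QSAR model on a descriptor subset
#'
#' Least squares with intercept on the named support columns. The design
#' must be full rank; rank deficiency is reported with the offending
#' column names.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @param y numeric activity vector aligned with the rows of `X` (matched
#'   by name when both carry names, otherwise by position).
#' @param support descriptor names to fit on; defaults to all columns.
#' @param name optional model label.
#' @return list with `model` (a [qsar_model()]) and `stats` (class
#'   `fit_stats`: `sse`, `see`, `r2`, `n_obs`, `n_params`).
#' @export
fit_ols <- function(X, y, support = colnames(X), name = NULL) {
  check_descriptor_matrix(X)
  missing <- setdiff(support, colnames(X))
  if (length(missing) > 0) {
    stop(sprintf("support descriptor(s) not in matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  y <- align_activities(X, y)
  p <- length(support)
  n <- nrow(X)
  if (n < p + 2) {
    stop(sprintf("need at least %d rows to fit %d descriptors", p + 2, p),
         call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, X[, support, drop = FALSE])
  fit <- stats::lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  coefs <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  stats <- structure(list(
    sse = sse,
    see = sqrt(sse / (n - p - 1)),
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    n_obs = n,
    n_params = p
  ), class = "fit_stats")
  list(model = qsar_model(support, coefs[-1], coefs[1], name = name),
       stats = stats)
}

# Align an activity vector with the rows of X: by name when both are
# named (order-independent), otherwise by position.
align_activities <- function(X, y) {
  if (!is.numeric(y)) stop("activities must be numeric", call. = FALSE)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    missing <- setdiff(rownames(X), names(y))
    if (length(missing) > 0) {
      stop(sprintf("no activity for compound(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    y <- y[rownames(X)]
  } else if (length(y) != nrow(X)) {
    stop("activity vector length does not match descriptor matrix rows",
         call. = FALSE)
  }
  unname(y)
}

#' Friedman lack-of-fit score
#'
#' LOF = (SSE / M) / (1 - (c + d * p) / M)^2, a mean squared error
#' penalized for equation size: `c` counts the non-intercept basis terms
#' and `p` all fitted parameters (descriptors plus intercept), so larger
#' equations pay a growing penalty controlled by the smoothing parameter
#' `d`.
#'
#' @param sse residual sum of squares of the fitted equation.
#' @param m number of training compounds.
#' @param c number of non-intercept model terms.
#' @param p total number of fitted parameters (defaults to `c + 1`).
#' @param d smoothing parameter (>= 0); larger values penalize equation
#'   size more strongly. The default (2) sits in the cost range Friedman
#'   recommends for smoother penalties; see Details.
#'
#' @details When equations of different sizes compete over a pool of
#' candidate descriptors, the winning extra descriptor is the best of
#' many, so the expected SSE drop from enlarging an equation is several
#' times a single chi-square draw. A mild smoothing (d = 0.5) makes the
#' size penalty between a k- and a (k+1)-descriptor equation smaller
#' than that selection-driven drop for pools of a few dozen descriptors,
#' so the larger equation practically always scores better; d = 2 makes
#' the penalty exceed it, which is why it is the search default here.
#' @return the lack-of-fit score (>= 0, monotone in `sse`).
#' @export
lof <- function(sse, m, c, p = c + 1, d = 2) {
  if (!is.numeric(sse) || sse < 0) stop("sse must be >= 0", call. = FALSE)
  if (m <= 0) stop("m must be positive", call. = FALSE)
  if (d < 0) stop("smoothing parameter d must be >= 0", call. = FALSE)
  denom <- 1 - (c + d * p) / m
  if (denom <= 0) {
    stop(sprintf(
      "over-parameterized equation: 1 - (c + d*p)/M = %.4f <= 0 (c=%g, p=%g, M=%g)",
      denom, c, p, m), call. = FALSE)
  }
  (sse / m) / denom^2
}

#' GFA configuration
#'
#' @param population_size number of candidate equations per generation.
#' @param generations number of generations to evolve.
#' @param model_size_min,model_size_max allowed descriptor counts per
#'   equation.
#' @param mutation_prob per-child probability of a mutation (add, remove
#'   or swap one descriptor, respecting the size bounds).
#' @param smoothing_d Friedman smoothing parameter `d`; see [lof()] for
#'   why the search default is 2.
#' @param elitism number of best equations copied unchanged each
#'   generation.
#' @param seed integer seed driving the whole run.
#' @return list of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 100, generations = 200,
                       model_size_min = 3, model_size_max = 5,
                       mutation_prob = 0.15, smoothing_d = 2,
                       elitism = 2, seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            model_size_min >= 1, model_size_max >= model_size_min,
            mutation_prob >= 0, mutation_prob <= 1,
            smoothing_d >= 0, elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 model_size_min = as.integer(model_size_min),
                 model_size_max = as.integer(model_size_max),
                 mutation_prob = mutation_prob,
                 smoothing_d = smoothing_d,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "gfa_config")
}

#' Rank candidate models by lack-of-fit
#'
#' @param candidates list of candidate records, each carrying a `lof`
#'   component.
#' @return the list reordered by ascending LOF; ties keep input order.
#' @export
rank_models <- function(candidates) {
  lofs <- vapply(candidates, function(c) c$lof, numeric(1))
  candidates[order(lofs)]  # order() is a stable sort: ties keep input order
}

#' Genetic function approximation over descriptor subsets
#'
#' Searches subsets of the descriptor columns for the multiple linear
#' regression with the lowest Friedman lack-of-fit. A population of
#' candidate supports evolves by tournament selection, union crossover
#' (each child support is drawn from the union of its parents'
#' descriptors) and add/remove/swap mutation; equation sizes stay within
#' the configured bounds. The best-so-far LOF is non-increasing across
#' generations and the whole run is reproducible from `config$seed`.
#'
#' @param X pretreated numeric descriptor matrix.
#' @param y activity vector aligned with `X` rows.
#' @param config a [gfa_config()].
#' @param top_k number of distinct best equations to return fully fitted.
#' @param initial_population optional list of integer column-index
#'   vectors used as the starting population (sizes must respect the
#'   configured bounds); when longer than `population_size` the whole
#'   list is still evaluated in the first generation.
#' @return object of class `gfa_result`: `ranked_models` (list of
#'   records with `model`, `stats`, `lof`), `best_lof_history`
#'   (per-generation best-so-far) and the `config`.
#' @export
gfa <- function(X, y, config = gfa_config(), top_k = 10,
                initial_population = NULL) {
  check_descriptor_matrix(X)
  y <- align_activities(X, y)
  nd <- ncol(X)
  n <- nrow(X)
  if (config$model_size_max > nd) {
    stop(sprintf("model_size_max (%d) exceeds descriptor count (%d)",
                 config$model_size_max, nd), call. = FALSE)
  }
  if (n < config$model_size_max + 2) {
    stop("too few compounds for the largest allowed equation", call. = FALSE)
  }

  set.seed(config$seed)
  sizes <- config$model_size_min:config$model_size_max
  m <- n

  # fitness cache keyed by the sorted support
  cache <- new.env(parent = emptyenv())
  eval_support <- function(s) {
    s <- sort(s)
    key <- paste(s, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    design <- cbind(1, X[, s, drop = FALSE])
    fit <- stats::.lm.fit(design, y)
    val <- if (fit$rank < ncol(design)) {
      Inf  # collinear support: unusable equation
    } else {
      sse <- sum(fit$residuals^2)
      lof(sse, m, c = length(s), p = length(s) + 1, d = config$smoothing_d)
    }
    cache[[key]] <- val
    val
  }
  pick_one <- function(v) v[sample.int(length(v), 1)]  # sample() would expand a scalar
  random_support <- function() sort(sample.int(nd, pick_one(sizes)))

  if (is.null(initial_population)) {
    pop <- replicate(config$population_size, random_support(),
                     simplify = FALSE)
  } else {
    sz <- lengths(initial_population)
    if (any(sz < config$model_size_min | sz > config$model_size_max)) {
      stop("initial population supports violate the size bounds",
           call. = FALSE)
    }
    pop <- lapply(initial_population, sort)
  }
  fitness <- vapply(pop, eval_support, numeric(1))
  best_hist <- numeric(config$generations)
  best_lof <- min(fitness)

  tournament <- function() {
    pair <- sample.int(length(pop), 2)
    if (fitness[pair[1]] <= fitness[pair[2]]) pair[1] else pair[2]
  }
  mutate <- function(s) {
    moves <- c(if (length(s) < config$model_size_max && length(s) < nd) "add",
               if (length(s) > config$model_size_min) "remove",
               if (length(s) < nd) "swap")
    if (length(moves) == 0) return(s)
    outside <- setdiff(seq_len(nd), s)
    switch(pick_one(moves),
           add = c(s, pick_one(outside)),
           remove = s[-sample.int(length(s), 1)],
           swap = c(s[-sample.int(length(s), 1)], pick_one(outside)))
  }

  for (gen in seq_len(config$generations)) {
    ord <- order(fitness)
    elite <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
    children <- vector("list", config$population_size - length(elite))
    for (i in seq_along(children)) {
      p1 <- pop[[tournament()]]
      p2 <- pop[[tournament()]]
      pool <- union(p1, p2)
      size <- min(pick_one(c(length(p1), length(p2))), length(pool))
      child <- sort(pool[sample.int(length(pool), size)])
      if (stats::runif(1) < config$mutation_prob) child <- sort(mutate(child))
      children[[i]] <- child
    }
    pop <- c(elite, children)
    fitness <- vapply(pop, eval_support, numeric(1))
    best_lof <- min(best_lof, fitness)
    best_hist[gen] <- best_lof
  }

  # distinct supports seen anywhere in the search, best first
  keys <- ls(cache)
  lofs <- vapply(keys, function(k) cache[[k]], numeric(1))
  ord <- order(lofs)
  take <- keys[ord][seq_len(min(top_k, sum(is.finite(lofs))))]
  ranked <- lapply(take, function(k) {
    s <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    f <- fit_ols(X, y, support = colnames(X)[s])
    list(model = f$model, stats = f$stats, lof = cache[[k]])
  })
  structure(list(ranked_models = rank_models(ranked),
                 best_lof_history = best_hist,
                 config = config),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("GFA search: %d generations, best LOF %.6g\n",
              length(x$best_lof_history),
              x$best_lof_history[length(x$best_lof_history)]))
  best <- x$ranked_models[[1]]
  cat(sprintf("  best equation (%d descriptors): %s\n",
              length(best$model$descriptors),
              paste(best$model$descriptors, collapse = " + ")))
  cat(sprintf("  R2 = %.4f, SEE = %.4f\n", best$stats$r2, best$stats$see))
  invisible(x)
}
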