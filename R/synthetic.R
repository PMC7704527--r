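#' Specification for a synthetic QSAR dataset
#'
#' Describes a descriptor/activity dataset with known ground truth:
#' standard-normal descriptors with exchangeable within-block
#' correlation, a planted linear activity model over a small support,
#' Gaussian activity noise, and optional nuisance columns (constant and
#' duplicated descriptors) for exercising pretreatment.
#'
#' @param n_compounds number of compounds (rows).
#' @param n_descriptors number of informative-pool descriptors before
#'   nuisance columns are appended.
#' @param support integer indices (within 1..n_descriptors) of the
#'   descriptors that truly drive the activity.
#' @param true_coefficients numeric, one per support descriptor.
#' @param intercept activity intercept; activities are generated directly
#'   on the pIC50 scale, so the default centres them near 5.
#' @param noise_sd standard deviation of the Gaussian activity noise.
#' @param descriptor_correlation exchangeable correlation within each
#'   descriptor block (0 <= r < 1).
#' @param block_size number of descriptors per correlated block.
#' @param n_constant number of constant nuisance columns appended.
#' @param n_duplicate number of duplicated nuisance columns appended
#'   (each an exact copy of one pool descriptor).
#' @param seed integer seed; regeneration with the same spec is
#'   bit-identical.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_descriptors, support,
                           true_coefficients, intercept = 5,
                           noise_sd = 0.1, descriptor_correlation = 0,
                           block_size = 5, n_constant = 0, n_duplicate = 0,
                           seed = 1L) {
  support <- as.integer(support)
  if (length(support) == 0 || any(support < 1 | support > n_descriptors) ||
      anyDuplicated(support)) {
    stop("support must be distinct indices in 1..n_descriptors", call. = FALSE)
  }
  if (length(true_coefficients) != length(support)) {
    stop("one true coefficient per support descriptor required", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (descriptor_correlation < 0 || descriptor_correlation >= 1) {
    stop("descriptor_correlation must be in [0, 1)", call. = FALSE)
  }
  if (n_compounds < length(support) + 3) {
    stop("too few compounds for the planted model", call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 support = support,
                 true_coefficients = as.numeric(true_coefficients),
                 intercept = as.numeric(intercept),
                 noise_sd = as.numeric(noise_sd),
                 descriptor_correlation = as.numeric(descriptor_correlation),
                 block_size = as.integer(block_size),
                 n_constant = as.integer(n_constant),
                 n_duplicate = as.integer(n_duplicate),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic QSAR dataset
#'
#' Draws descriptors row-wise standard normal, imposes exchangeable
#' correlation within consecutive blocks of `block_size` columns via the
#' Cholesky factor of the exchangeable correlation matrix, computes
#' activities from the planted linear model plus Gaussian noise, and
#' appends the requested nuisance columns (constants, then exact
#' duplicates of randomly chosen pool descriptors).
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset`: `descriptors` (matrix with
#'   compound/descriptor names), `activities` (named vector), `truth`
#'   (the generating [synthetic_spec()] plus the support/nuisance column
#'   names).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  p <- spec$n_descriptors
  Z <- matrix(stats::rnorm(n * p), n, p)
  rho <- spec$descriptor_correlation
  if (rho > 0) {
    starts <- seq(1, p, by = spec$block_size)
    for (s in starts) {
      e <- min(s + spec$block_size - 1L, p)
      b <- e - s + 1L
      if (b < 2) next
      R <- matrix(rho, b, b); diag(R) <- 1
      L <- chol(R)  # upper triangular: Z %*% L has correlation R row-wise
      Z[, s:e] <- Z[, s:e, drop = FALSE] %*% L
    }
  }
  desc_names <- sprintf("D%03d", seq_len(p))
  dimnames(Z) <- list(sprintf("C%03d", seq_len(n)), desc_names)

  y <- spec$intercept +
    drop(Z[, spec$support, drop = FALSE] %*% spec$true_coefficients) +
    stats::rnorm(n, 0, spec$noise_sd)

  const_names <- dup_names <- character(0)
  if (spec$n_constant > 0) {
    const_names <- sprintf("CONST%02d", seq_len(spec$n_constant))
    Z <- cbind(Z, matrix(2, n, spec$n_constant,
                         dimnames = list(NULL, const_names)))
  }
  if (spec$n_duplicate > 0) {
    src <- sample.int(p, spec$n_duplicate, replace = TRUE)
    dup_names <- sprintf("DUP%02d_%s", seq_len(spec$n_duplicate),
                         desc_names[src])
    D <- Z[, desc_names[src], drop = FALSE]
    colnames(D) <- dup_names
    Z <- cbind(Z, D)
  }
  truth <- c(unclass(spec),
             list(support_names = desc_names[spec$support],
                  constant_names = const_names,
                  duplicate_names = dup_names))
  structure(list(descriptors = Z,
                 activities = stats::setNames(y, rownames(Z)),
                 truth = truth),
            class = "synthetic_dataset")
}

#' Benchmark dataset presets
#'
#' Canned difficulty settings for end-to-end tests of the pipeline:
#' \describe{
#'   \item{easy}{40 compounds, 30 descriptors, 4 true descriptors spread
#'     over distinct mildly correlated blocks (r = 0.2), activity noise
#'     sd 0.05 — the descriptor-selection search should recover the
#'     planted support almost always.}
#'   \item{paper_like}{39 compounds and 1000 columns before pretreatment
#'     (960 informative pool, 20 constant, 20 duplicated), 4 true
#'     descriptors, within-block correlation 0.3, noise sd 0.2 — the
#'     shape of a realistic descriptor-calculator export.}
#'   \item{hard}{like easy but each true descriptor sits in a block of
#'     decoys correlated at r = 0.9 and noise sd 0.2 — support recovery
#'     is only partial by design.}
#' }
#'
#' @param preset one of "easy", "paper_like", "hard".
#' @param seed integer seed.
#' @return a `synthetic_dataset`; its `truth` record carries the preset
#'   name.
#' @export
make_benchmark <- function(preset = c("easy", "paper_like", "hard"),
                           seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    easy = synthetic_spec(
      n_compounds = 40, n_descriptors = 30,
      support = c(1L, 6L, 11L, 16L),
      true_coefficients = c(0.6, -0.45, 0.35, -0.25),
      intercept = 5, noise_sd = 0.05,
      descriptor_correlation = 0.2, block_size = 5, seed = seed),
    paper_like = synthetic_spec(
      n_compounds = 39, n_descriptors = 960,
      support = c(1L, 11L, 21L, 31L),
      true_coefficients = c(0.6, -0.45, 0.35, -0.25),
      intercept = 5, noise_sd = 0.2,
      descriptor_correlation = 0.3, block_size = 10,
      n_constant = 20, n_duplicate = 20, seed = seed),
    hard = synthetic_spec(
      n_compounds = 40, n_descriptors = 30,
      support = c(1L, 6L, 11L, 16L),
      true_coefficients = c(0.6, -0.45, 0.35, -0.25),
      intercept = 5, noise_sd = 0.2,
      descriptor_correlation = 0.9, block_size = 5, seed = seed))
  ds <- generate_dataset(spec)
  ds$truth$preset <- preset
  ds
}

#' Inject named pathologies into a synthetic dataset
#'
#' Adds data defects that the ingest/pretreatment stages must handle:
#' \describe{
#'   \item{constant}{appends an all-constant descriptor column
#'     `PATH_CONST`.}
#'   \item{duplicate}{appends `PATH_DUP`, an exact copy of the first
#'     descriptor column.}
#'   \item{missing}{blanks one descriptor cell (recorded in the truth
#'     manifest as `missing_cell`), so a round-trip through the CSV
#'     reader must fail with the cell's coordinates.}
#' }
#'
#' @param dataset a `synthetic_dataset`.
#' @param kinds subset of c("constant", "duplicate", "missing").
#' @return the modified `synthetic_dataset`.
#' @export
inject_pathologies <- function(dataset, kinds) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  unknown <- setdiff(kinds, c("constant", "duplicate", "missing"))
  if (length(unknown) > 0) {
    stop(sprintf("unknown pathology kind(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  X <- dataset$descriptors
  if ("constant" %in% kinds) {
    X <- cbind(X, PATH_CONST = rep(2, nrow(X)))
    dataset$truth$pathology_constant <- "PATH_CONST"
  }
  if ("duplicate" %in% kinds) {
    X <- cbind(X, PATH_DUP = X[, 1])
    dataset$truth$pathology_duplicate <-
      c(source = colnames(X)[1], copy = "PATH_DUP")
  }
  if ("missing" %in% kinds) {
    X[1, 2] <- NA_real_
    dataset$truth$missing_cell <- c(row = rownames(X)[1],
                                    column = colnames(X)[2])
  }
  dataset$descriptors <- X
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Emits the descriptor CSV, the activity CSV and a truth-manifest JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    descriptors = file.path(dir, paste0(prefix, "_descriptors.csv")),
    activities = file.path(dir, paste0(prefix, "_activities.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  df <- data.frame(compound_id = rownames(dataset$descriptors),
                   dataset$descriptors, check.names = FALSE)
  utils::write.csv(df, paths["descriptors"], row.names = FALSE, na = "")
  utils::write.csv(
    data.frame(compound_id = names(dataset$activities),
               pic50 = as.numeric(dataset$activities)),
    paths["activities"], row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
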