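#' Read a descriptor matrix from CSV
#'
#' The first column holds compound identifiers; every remaining column is
#' a named numeric molecular descriptor (as exported by a descriptor
#' calculator). Row and column labels must be unique and every cell must
#' parse as a finite number — missing or non-numeric cells are reported
#' with their coordinates.
#'
#' @param path path to a CSV file.
#' @return numeric matrix, compounds as rownames, descriptors as colnames.
#' @export
read_descriptor_matrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2) {
    stop("descriptor table has no descriptor columns: ", path, call. = FALSE)
  }
  if (nrow(raw) == 0) stop("descriptor table is empty: ", path, call. = FALSE)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate compound id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  desc_names <- names(raw)[-1]
  dupc <- unique(desc_names[duplicated(desc_names)])
  if (length(dupc) > 0) {
    stop(sprintf("duplicate descriptor name(s): %s", paste(dupc, collapse = ", ")),
         call. = FALSE)
  }
  X <- matrix(NA_real_, nrow(raw), length(desc_names),
              dimnames = list(ids, desc_names))
  for (j in seq_along(desc_names)) {
    txt <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell '%s' at row %d (compound %s), column '%s'",
                   txt[bad[1]], bad[1], ids[bad[1]], desc_names[j]),
           call. = FALSE)
    }
    X[, j] <- val
  }
  X
}

#' Write a descriptor matrix to CSV
#'
#' @param X numeric matrix with compound rownames and descriptor colnames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(X, path) {
  df <- data.frame(compound_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

check_descriptor_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("descriptor matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop("descriptor matrix needs compound rownames and descriptor colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X)) || anyDuplicated(colnames(X))) {
    stop("descriptor matrix labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop("descriptor matrix contains non-finite values", call. = FALSE)
  }
  invisible(X)
}

#' Pretreat a descriptor matrix
#'
#' Removes uninformative descriptors: columns whose variance is at or
#' below `variance_tol` (near-constant) and, for every pair with absolute
#' Pearson correlation at or above `corr_threshold`, the later column in
#' input order (keep-first rule). The operation is idempotent.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @param variance_tol variance at or below this is treated as constant.
#' @param corr_threshold absolute pairwise correlation at or above this
#'   drops the later column of the pair.
#' @return list with components `matrix` (the surviving columns) and
#'   `report`, an object of class `pretreat_report` listing
#'   `removed_constant`, `removed_correlated` (data.frame kept/dropped/r)
#'   and `n_kept`.
#' @export
pretreat <- function(X, variance_tol = 1e-8, corr_threshold = 0.99) {
  check_descriptor_matrix(X)
  vars <- apply(X, 2, stats::var)
  const <- colnames(X)[vars <= variance_tol]
  keep <- setdiff(colnames(X), const)
  if (length(keep) == 0) {
    stop("pretreatment removed every descriptor (all near-constant)",
         call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  kept_pairs <- character(0)
  dropped <- character(0)
  rvals <- numeric(0)
  if (ncol(Xk) >= 2) {
    cm <- abs(stats::cor(Xk))
    alive <- rep(TRUE, ncol(Xk))
    for (j in 2:ncol(Xk)) {
      earlier <- which(alive[seq_len(j - 1L)])
      if (length(earlier) == 0) next
      hits <- earlier[cm[earlier, j] >= corr_threshold]
      if (length(hits) > 0) {
        alive[j] <- FALSE
        kept_pairs <- c(kept_pairs, colnames(Xk)[hits[1]])
        dropped <- c(dropped, colnames(Xk)[j])
        rvals <- c(rvals, stats::cor(Xk[, hits[1]], Xk[, j]))
      }
    }
    Xk <- Xk[, alive, drop = FALSE]
  }
  if (ncol(Xk) == 0) {
    stop("pretreatment removed every descriptor", call. = FALSE)
  }
  report <- structure(list(
    removed_constant = const,
    removed_correlated = data.frame(kept = kept_pairs, dropped = dropped,
                                    r = rvals, stringsAsFactors = FALSE),
    n_kept = ncol(Xk),
    variance_tol = variance_tol,
    corr_threshold = corr_threshold
  ), class = "pretreat_report")
  list(matrix = Xk, report = report)
}

#' @export
print.pretreat_report <- function(x, ...) {
  cat("Descriptor pretreatment report\n")
  cat(sprintf("  near-constant removed : %d\n", length(x$removed_constant)))
  cat(sprintf("  collinear removed     : %d (|r| >= %g)\n",
              nrow(x$removed_correlated), x$corr_threshold))
  cat(sprintf("  descriptors kept      : %d\n", x$n_kept))
  invisible(x)
}

#' Kennard-Stone calibration/validation split
#'
#' Greedy maximin selection on Euclidean distances between
#' column-standardized descriptor rows: the first two picks are a
#' globally maximally distant pair; each later pick maximizes its minimum
#' distance to the already-selected set. Ties are broken by the smallest
#' input row index, so the split is reproducible. Standardization uses
#' the mean and standard deviation of the full compound set.
#'
#' @param X numeric descriptor matrix (compounds x descriptors).
#' @param n_train number of calibration compounds to select (2..N).
#' @param train_fraction alternative to `n_train`: selects
#'   `floor(train_fraction * N)` compounds (e.g. 0.7 of 39 gives 27).
#' @return object of class `data_split`: list with `train_ids` and
#'   `test_ids` character vectors.
#' @export
kennard_stone <- function(X, n_train = NULL, train_fraction = NULL) {
  check_descriptor_matrix(X)
  n <- nrow(X)
  if (is.null(n_train)) {
    if (is.null(train_fraction)) {
      stop("give either n_train or train_fraction", call. = FALSE)
    }
    if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction > 1) {
      stop("train_fraction must be in (0, 1]", call. = FALSE)
    }
    n_train <- floor(train_fraction * n)
  }
  if (!is.numeric(n_train) || n_train != round(n_train) ||
      n_train < 2 || n_train > n) {
    stop(sprintf("n_train must be an integer in [2, %d]", n), call. = FALSE)
  }
  n_train <- as.integer(n_train)

  sds <- apply(X, 2, stats::sd)
  Z <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  D <- as.matrix(stats::dist(Z))

  # first pair: global maximum distance, ties by smallest (i, j)
  sel <- integer(0)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > best) { best <- D[i, j]; bi <- i; bj <- j }
    }
  }
  sel <- c(bi, bj)
  if (n_train > 2L) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- pmin(D[remaining, bi], D[remaining, bj])
    for (step in 3:n_train) {
      pick <- remaining[which.max(mind)]  # which.max takes the first maximum
      sel <- c(sel, pick)
      keep <- remaining != pick
      remaining <- remaining[keep]
      mind <- pmin(mind[keep], D[remaining, pick])
    }
  }
  sel <- sel[seq_len(n_train)]
  structure(list(train_ids = rownames(X)[sel],
                 test_ids = rownames(X)[setdiff(seq_len(n), sel)]),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d calibration, %d validation compounds\n",
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' Write a data split to CSV
#'
#' Emits two columns, `compound_id` and `set` (train/test).
#'
#' @param split a `data_split` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    compound_id = c(split$train_ids, split$test_ids),
    set = c(rep("train", length(split$train_ids)),
            rep("test", length(split$test_ids))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a data split from CSV
#'
#' @param path CSV with columns `compound_id` and `set` in {train, test}.
#' @return a `data_split` object.
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("compound_id", "set") %in% names(df))) {
    stop("split file needs columns compound_id and set", call. = FALSE)
  }
  if (!all(df$set %in% c("train", "test"))) {
    stop("split 'set' values must be 'train' or 'test'", call. = FALSE)
  }
  structure(list(train_ids = df$compound_id[df$set == "train"],
                 test_ids = df$compound_id[df$set == "test"]),
            class = "data_split")
}
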