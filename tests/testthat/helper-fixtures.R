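# Shared helpers: small deterministic matrices and CSV scratch files.

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# random named descriptor matrix
random_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("c%02d", seq_len(n)),
                         sprintf("d%02d", seq_len(p))))
}

# 1-D descriptor matrix from a numeric vector
one_d_matrix <- function(x, ids = letters[seq_along(x)]) {
  matrix(x, ncol = 1, dimnames = list(ids, "x"))
}

table3_fixture <- function() {
  utils::read.csv(qsarlab_example("table3_external_validation.csv"))
}

# independent pretreat oracle: literal per-column / per-pair scan
oracle_pretreat <- function(X, variance_tol = 1e-8, corr_threshold = 0.99) {
  const <- character(0)
  for (nm in colnames(X)) {
    if (stats::var(X[, nm]) <= variance_tol) const <- c(const, nm)
  }
  left <- setdiff(colnames(X), const)
  kept <- character(0)
  dropped <- character(0)
  for (nm in left) {
    hit <- FALSE
    for (k in kept) {
      if (abs(stats::cor(X[, k], X[, nm])) >= corr_threshold) hit <- TRUE
    }
    if (hit) dropped <- c(dropped, nm) else kept <- c(kept, nm)
  }
  list(constant = const, kept = kept, dropped = dropped)
}
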