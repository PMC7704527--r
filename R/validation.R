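#' Coefficient of determination about a reference mean
#'
#' R2 = 1 - sum((y_obs - y_pred)^2) / sum((y_obs - ref_mean)^2). The
#' reference mean defaults to the mean of `y_obs`; for external
#' validation pass the training-set mean so the total sum of squares is
#' taken about the calibration activities.
#'
#' @param y_obs observed activities.
#' @param y_pred predicted activities, same length.
#' @param ref_mean reference mean for the total sum of squares; defaults
#'   to `mean(y_obs)`.
#' @return R2 (scalar).
#' @export
r_squared <- function(y_obs, y_pred, ref_mean = NULL) {
  if (length(y_obs) != length(y_pred)) {
    stop("observed and predicted vectors differ in length", call. = FALSE)
  }
  if (length(y_obs) < 2) stop("need at least 2 points", call. = FALSE)
  if (is.null(ref_mean)) ref_mean <- mean(y_obs)
  ss_tot <- sum((y_obs - ref_mean)^2)
  if (ss_tot <= 0) {
    stop("zero total sum of squares: observations do not vary about the reference mean",
         call. = FALSE)
  }
  1 - sum((y_obs - y_pred)^2) / ss_tot
}

#' Adjusted coefficient of determination
#'
#' Standard (Ezekiel) correction for the number of fitted descriptors:
#' R2_adj = 1 - (1 - R2) * (n - 1) / (n - p - 1).
#'
#' @param r2 training R2.
#' @param n number of training compounds.
#' @param p number of descriptors in the equation.
#' @return adjusted R2.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("need n > p + 1 for the adjusted R2", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Leave-one-out cross-validated Q2
#'
#' For each training compound the equation is refit on the remaining
#' compounds (exact refit, no shortcut) and used to predict the held-out
#' activity. Q2 = 1 - PRESS / sum((y_i - mean(y))^2), with the mean taken
#' over the full training set.
#'
#' @param X descriptor matrix of the training compounds.
#' @param y training activities aligned with `X`.
#' @param support descriptor names of the equation.
#' @return list with `q2`, `press` and `loo_predictions` (named vector).
#' @export
q2_loo <- function(X, y, support = colnames(X)) {
  check_descriptor_matrix(X)
  y <- align_activities(X, y)
  n <- nrow(X)
  if (n < length(support) + 3) {
    stop("too few compounds for leave-one-out refits", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("activities are constant: Q2 undefined", call. = FALSE)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_ols(X[-i, , drop = FALSE], y[-i], support = support),
      error = function(e) {
        stop(sprintf("leave-one-out refit without compound '%s' failed: %s",
                     rownames(X)[i], conditionMessage(e)), call. = FALSE)
      })
    preds[i] <- predict(fit$model, X[i, , drop = FALSE])
  }
  press <- sum((preds - y)^2)
  list(q2 = 1 - press / ss_tot, press = press,
       loo_predictions = stats::setNames(preds, rownames(X)))
}

#' External validation: predictive R2 about the training mean
#'
#' R2_pred = 1 - SSres / SStot with SSres = sum((y_obs - y_pred)^2) over
#' the validation compounds and SStot = sum((y_obs - y_mintrn)^2) about
#' the mean activity of the calibration set.
#'
#' @param y_obs_test observed validation-set activities.
#' @param y_pred_test model predictions for the validation set.
#' @param y_mintrn mean activity of the calibration (training) set.
#' @return list of class `external_validation`: `y_mintrn`, `ss_res`,
#'   `ss_tot`, `r2_pred`, `n_test`.
#' @export
external_r2pred <- function(y_obs_test, y_pred_test, y_mintrn) {
  if (length(y_obs_test) == 0) stop("empty validation set", call. = FALSE)
  if (length(y_obs_test) != length(y_pred_test)) {
    stop("observed and predicted vectors differ in length", call. = FALSE)
  }
  if (!is.finite(y_mintrn)) stop("y_mintrn must be finite", call. = FALSE)
  ss_res <- sum((y_obs_test - y_pred_test)^2)
  ss_tot <- sum((y_obs_test - y_mintrn)^2)
  if (ss_tot <= 0) {
    stop("zero total sum of squares about the training mean", call. = FALSE)
  }
  structure(list(y_mintrn = y_mintrn, ss_res = ss_res, ss_tot = ss_tot,
                 r2_pred = 1 - ss_res / ss_tot,
                 n_test = length(y_obs_test)),
            class = "external_validation")
}

#' Descriptor mean effects
#'
#' Signed, normalized contribution of each descriptor to the equation's
#' predictions over a chosen compound set:
#' ME_j = beta_j * sum_i(D_ij) / sum_m(beta_m * sum_i(D_im)). The mean
#' effects sum to 1; the sign tells whether raising the descriptor raises
#' or lowers the predicted activity.
#'
#' @param model a [qsar_model()].
#' @param D descriptor matrix over the compound set of interest (training,
#'   validation, or all compounds).
#' @return named numeric vector of mean effects, one per model descriptor.
#' @export
mean_effect <- function(model, D) {
  if (is.data.frame(D)) D <- as.matrix(D)
  missing <- setdiff(model$descriptors, colnames(D))
  if (length(missing) > 0) {
    stop(sprintf("descriptor(s) missing from data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  csum <- colSums(D[, model$descriptors, drop = FALSE])
  contrib <- model$coefficients * csum
  denom <- sum(contrib)
  if (denom == 0) stop("mean-effect denominator is zero", call. = FALSE)
  stats::setNames(contrib / denom, model$descriptors)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R_j^2) where R_j^2 comes from regressing descriptor j
#' on the remaining support descriptors (with intercept). Values above 10
#' flag an unstable, collinear equation; a perfectly collinear descriptor
#' is reported as `Inf` rather than an error.
#'
#' @param D descriptor matrix.
#' @param support descriptor names to diagnose (>= 2).
#' @return named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
vif <- function(D, support = colnames(D)) {
  if (is.data.frame(D)) D <- as.matrix(D)
  if (length(support) < 2) stop("VIF needs at least 2 descriptors", call. = FALSE)
  missing <- setdiff(support, colnames(D))
  if (length(missing) > 0) {
    stop(sprintf("descriptor(s) missing from data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(D) <= length(support)) {
    stop("need more compounds than descriptors for VIF", call. = FALSE)
  }
  out <- numeric(length(support))
  for (j in seq_along(support)) {
    yj <- D[, support[j]]
    Xj <- cbind(1, D[, support[-j], drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    sst <- sum((yj - mean(yj))^2)
    if (sst <= 0) stop(sprintf("descriptor '%s' is constant", support[j]),
                       call. = FALSE)
    r2j <- 1 - sum(fit$residuals^2) / sst
    out[j] <- if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }
  stats::setNames(pmax(out, 1), support)
}

#' Pairwise descriptor correlation matrix
#'
#' @param D descriptor matrix.
#' @param support descriptor names to include.
#' @return symmetric Pearson correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(D, support = colnames(D)) {
  if (is.data.frame(D)) D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 compounds", call. = FALSE)
  sub <- D[, support, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance descriptor(s): %s",
                 paste(support[sds == 0], collapse = ", ")), call. = FALSE)
  }
  cm <- stats::cor(sub)
  diag(cm) <- 1
  cm
}

#' Leverages (hat-matrix diagonal)
#'
#' h_i = x_i (X^T X)^{-1} x_i^T with an intercept column appended to the
#' training design. For training rows this is the hat-matrix diagonal
#' (each h_i in \[0, 1\], summing to k + 1); the same quadratic form is
#' evaluated for query rows, where values above the warning leverage mark
#' extrapolation outside the calibration domain.
#'
#' @param X_train training descriptor matrix restricted to the model
#'   support.
#' @param X_query optional query rows over the same descriptors; when
#'   given, their leverages are returned instead of the training ones.
#' @return numeric vector of leverages, named by compound.
#' @export
leverage <- function(X_train, X_query = NULL) {
  if (is.data.frame(X_train)) X_train <- as.matrix(X_train)
  A <- cbind(1, X_train)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop("rank-deficient training design: leverages undefined", call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qrA))
  target <- if (is.null(X_query)) X_train else {
    if (is.data.frame(X_query)) X_query <- as.matrix(X_query)
    if (!is.null(colnames(X_train)) && !is.null(colnames(X_query))) {
      missing <- setdiff(colnames(X_train), colnames(X_query))
      if (length(missing) > 0) {
        stop(sprintf("query rows lack descriptor(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      X_query <- X_query[, colnames(X_train), drop = FALSE]
    }
    X_query
  }
  B <- cbind(1, target)
  h <- rowSums((B %*% XtXinv) * B)
  stats::setNames(h, rownames(target))
}

#' Warning leverage of the applicability domain
#'
#' h* = 3 (k + 1) / n, where k is the number of descriptors in the
#' equation and n the number of calibration compounds. Compounds with
#' leverage above h* lie outside the reliable prediction domain.
#'
#' @param k number of model descriptors.
#' @param n number of calibration compounds.
#' @return the warning leverage (scalar).
#' @export
warning_leverage <- function(k, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  3 * (k + 1) / n
}

#' Williams-plot table
#'
#' Combines leverages and standardized residuals (residual divided by the
#' training SEE) into the plot-ready applicability-domain table: a
#' compound is flagged a response outlier when |standardized residual|
#' exceeds `resid_limit` (default 3) and a leverage outlier when its
#' leverage strictly exceeds the warning leverage.
#'
#' @param leverages named leverage vector.
#' @param residuals raw residuals (observed - predicted), same order.
#' @param see training standard error of estimate.
#' @param h_star warning leverage.
#' @param resid_limit standardized-residual cutoff.
#' @return data.frame of class `domain_assessment`: compound_id,
#'   leverage, std_residual, high_leverage, outlier, in_domain.
#' @export
williams_data <- function(leverages, residuals, see, h_star,
                          resid_limit = 3) {
  if (length(leverages) != length(residuals)) {
    stop("leverages and residuals differ in length", call. = FALSE)
  }
  if (see <= 0) {
    if (any(residuals != 0)) {
      stop("SEE is zero but residuals are not: standardized residuals undefined",
           call. = FALSE)
    }
    std_res <- residuals
  } else {
    std_res <- residuals / see
  }
  ids <- names(leverages)
  if (is.null(ids)) ids <- as.character(seq_along(leverages))
  out <- data.frame(
    compound_id = ids,
    leverage = as.numeric(leverages),
    std_residual = as.numeric(std_res),
    high_leverage = as.numeric(leverages) > h_star,  # strict: h == h* is in-domain
    outlier = abs(std_res) > resid_limit,
    stringsAsFactors = FALSE)
  out$in_domain <- !out$high_leverage & !out$outlier
  attr(out, "h_star") <- h_star
  attr(out, "see") <- see
  class(out) <- c("domain_assessment", "data.frame")
  out
}

#' Judge a model against the recommended QSAR acceptance thresholds
#'
#' The field's minimum recommended values for a usable equation:
#' training R2 >= 0.6, leave-one-out Q2 >= 0.5, R2 - Q2 < 0.3, at least 5
#' validation compounds, and external R2 >= 0.5. A confidence-level
#' criterion (p < 0.05) is carried in the table but reported as not
#' evaluated, since no test statistic is attached to it here; it does not
#' enter the overall verdict.
#'
#' @param r2 training R2.
#' @param q2 leave-one-out Q2.
#' @param r2_ext external (predictive) R2.
#' @param n_test number of validation compounds.
#' @return data.frame of class `golden_criteria` with columns criterion,
#'   threshold, value, pass; attribute `overall` is TRUE when every
#'   evaluated criterion passes.
#' @export
evaluate_against_criteria <- function(r2, q2, r2_ext, n_test) {
  tab <- data.frame(
    criterion = c("R2", "Q2", "R2 - Q2", "N test", "R2 ext", "P (95%)"),
    threshold = c(">= 0.6", ">= 0.5", "< 0.3", ">= 5", ">= 0.5", "< 0.05"),
    value = c(r2, q2, r2 - q2, n_test, r2_ext, NA_real_),
    pass = c(r2 >= 0.6, q2 >= 0.5, (r2 - q2) < 0.3, n_test >= 5,
             r2_ext >= 0.5, NA),
    stringsAsFactors = FALSE)
  attr(tab, "overall") <- all(tab$pass[!is.na(tab$pass)])
  class(tab) <- c("golden_criteria", "data.frame")
  tab
}

#' Full internal/external validation of one equation
#'
#' Convenience wrapper producing the complete validation report for a
#' descriptor support: training fit (R2, adjusted R2, SEE), leave-one-out
#' Q2, external predictive R2, descriptor diagnostics (VIF, mean effect,
#' correlation matrix), leverage-based domain assessment and the
#' recommended-threshold verdicts.
#'
#' @param X descriptor matrix over all compounds.
#' @param y activities aligned with `X`.
#' @param split a `data_split`.
#' @param support descriptor names of the equation.
#' @param mean_effect_set compound set for the mean effect: "train",
#'   "test" or "all".
#' @return list of class `validation_report`.
#' @export
validate_model <- function(X, y, split, support,
                           mean_effect_set = c("train", "test", "all")) {
  mean_effect_set <- match.arg(mean_effect_set)
  check_descriptor_matrix(X)
  y <- align_activities(X, y)
  names(y) <- rownames(X)
  bad <- setdiff(c(split$train_ids, split$test_ids), rownames(X))
  if (length(bad) > 0) {
    stop(sprintf("split names unknown compound(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Xtr <- X[split$train_ids, , drop = FALSE]
  Xte <- X[split$test_ids, , drop = FALSE]
  ytr <- y[split$train_ids]
  yte <- y[split$test_ids]

  fit <- fit_ols(Xtr, ytr, support = support)
  k <- length(support)
  n <- nrow(Xtr)
  loo <- q2_loo(Xtr, ytr, support = support)
  internal <- list(r2 = fit$stats$r2,
                   r2_adj = adjusted_r2(fit$stats$r2, n, k),
                   see = fit$stats$see,
                   q2_loo = loo$q2)

  pred_te <- predict(fit$model, Xte)
  external <- if (length(yte) > 0) {
    external_r2pred(yte, pred_te, mean(ytr))
  } else NULL

  D_me <- switch(mean_effect_set, train = Xtr, test = Xte, all = X)
  diagnostics <- list(
    correlation_matrix = correlation_matrix(Xtr, support),
    vif = vif(Xtr, support),
    mean_effect = mean_effect(fit$model, D_me))

  h_star <- warning_leverage(k, n)
  h_all <- c(leverage(Xtr[, support, drop = FALSE]),
             if (nrow(Xte) > 0)
               leverage(Xtr[, support, drop = FALSE],
                        Xte[, support, drop = FALSE]))
  resid_all <- c(ytr - predict(fit$model, Xtr), yte - pred_te)
  domain <- williams_data(h_all, resid_all, fit$stats$see, h_star)

  criteria <- evaluate_against_criteria(
    r2 = internal$r2, q2 = internal$q2_loo,
    r2_ext = if (is.null(external)) NA_real_ else external$r2_pred,
    n_test = length(yte))

  structure(list(model = fit$model, fit_stats = fit$stats,
                 internal = internal, external = external,
                 diagnostics = diagnostics, domain = domain,
                 warning_leverage = h_star, criteria = criteria),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("QSAR validation report\n")
  cat(sprintf("  equation: %s\n", paste(x$model$descriptors, collapse = " + ")))
  cat(sprintf("  internal: R2 = %.4f, R2adj = %.4f, SEE = %.4f, Q2(LOO) = %.4f\n",
              x$internal$r2, x$internal$r2_adj, x$internal$see, x$internal$q2_loo))
  if (!is.null(x$external)) {
    cat(sprintf("  external: R2pred = %.4f (SSres %.4f / SStot %.4f, n_test %d)\n",
                x$external$r2_pred, x$external$ss_res, x$external$ss_tot,
                x$external$n_test))
  }
  cat(sprintf("  applicability domain: h* = %.4f, %d/%d compounds in domain\n",
              x$warning_leverage, sum(x$domain$in_domain), nrow(x$domain)))
  cat(sprintf("  recommended thresholds: %s\n",
              if (attr(x$criteria, "overall")) "all evaluated criteria pass"
              else "FAILS at least one criterion"))
  invisible(x)
}
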