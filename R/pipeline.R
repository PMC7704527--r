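#' Path to a packaged example/fixture file
#'
#' The package ships transcriptions of the published study's tables:
#' `table3_external_validation.csv` (validation-set descriptors,
#' observed and printed predicted activities), `table5_activities.csv`
#' (all 39 compounds with printed predictions and calibration/validation
#' flags), `table10_properties.csv` (physicochemical properties of the
#' 18 designed compounds) and `published_models.json` (the four printed
#' equations).
#'
#' @param file fixture file name; when missing, lists the available
#'   files.
#' @return a file path (or a vector of file names).
#' @export
qsarlab_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "qsarlab")))
  }
  system.file("extdata", file, package = "qsarlab", mustWork = TRUE)
}

#' Run the complete QSAR study end-to-end
#'
#' Sequences the whole workflow on a descriptor matrix and activity
#' vector: pretreatment, Kennard-Stone calibration/validation split,
#' genetic-function-approximation model search on the calibration set,
#' full internal/external validation with applicability-domain analysis
#' of the best equation, and (optionally) a drug-likeness screen of a
#' property table. Deterministic given the configuration's seed.
#'
#' @param descriptors descriptor matrix, or path to a descriptor CSV.
#' @param activities named activity vector, or path to an activity CSV.
#' @param train_fraction Kennard-Stone calibration fraction (floor of
#'   fraction x N compounds); ignored when `n_train` is given.
#' @param n_train explicit calibration-set size.
#' @param gfa_config a [gfa_config()].
#' @param variance_tol,corr_threshold pretreatment settings.
#' @param properties optional property table (data.frame or CSV path)
#'   to screen for drug-likeness.
#' @param top_k number of ranked equations to keep in the report.
#' @return list of class `study_report`: pretreatment report, split,
#'   GFA result, validation report for the top equation, optional
#'   screening summary and a provenance record.
#' @export
run_full_study <- function(descriptors, activities,
                           train_fraction = 0.7, n_train = NULL,
                           gfa_config = qsarlab::gfa_config(),
                           variance_tol = 1e-8, corr_threshold = 0.99,
                           properties = NULL, top_k = 10) {
  if (is.character(descriptors)) {
    if (!file.exists(descriptors)) {
      stop("descriptor file not found: ", descriptors, call. = FALSE)
    }
    descriptors <- read_descriptor_matrix(descriptors)
  }
  if (is.character(activities)) {
    if (!file.exists(activities)) {
      stop("activity file not found: ", activities, call. = FALSE)
    }
    act <- read_compound_table(activities)
    activities <- stats::setNames(act$pic50, act$compound_id)
  }
  y <- align_activities(descriptors, activities)
  names(y) <- rownames(descriptors)

  pt <- pretreat(descriptors, variance_tol = variance_tol,
                 corr_threshold = corr_threshold)
  X <- pt$matrix
  split <- kennard_stone(X, n_train = n_train,
                         train_fraction = if (is.null(n_train)) train_fraction)
  Xtr <- X[split$train_ids, , drop = FALSE]
  ytr <- y[split$train_ids]

  gfa_res <- gfa(Xtr, ytr, config = gfa_config, top_k = top_k)
  best <- gfa_res$ranked_models[[1]]
  report <- validate_model(X, y, split, support = best$model$descriptors)

  screening <- if (!is.null(properties)) {
    if (is.character(properties)) properties <- read_property_table(properties)
    screen_table(properties)
  } else NULL

  structure(list(
    pretreatment = pt$report,
    split = split,
    gfa = gfa_res,
    validation = report,
    screening = screening,
    provenance = list(
      seed = gfa_config$seed,
      n_compounds = nrow(descriptors),
      n_descriptors_in = ncol(descriptors),
      n_descriptors_kept = ncol(X),
      n_train = length(split$train_ids),
      n_test = length(split$test_ids),
      package_version = as.character(utils::packageVersion("qsarlab")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("QSAR study report\n")
  cat(sprintf("  compounds: %d (%d calibration / %d validation)\n",
              x$provenance$n_compounds, x$provenance$n_train,
              x$provenance$n_test))
  cat(sprintf("  descriptors: %d in, %d after pretreatment\n",
              x$provenance$n_descriptors_in, x$provenance$n_descriptors_kept))
  print(x$validation)
  if (!is.null(x$screening)) print(x$screening)
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  best <- report$gfa$ranked_models[[1]]
  obj <- list(
    provenance = report$provenance,
    pretreatment = unclass(report$pretreatment),
    split = unclass(report$split),
    best_model = list(name = best$model$name,
                      descriptors = best$model$descriptors,
                      coefficients = best$model$coefficients,
                      intercept = best$model$intercept,
                      lof = best$lof),
    internal = report$validation$internal,
    external = if (!is.null(report$validation$external))
      unclass(report$validation$external),
    diagnostics = list(
      vif = as.list(report$validation$diagnostics$vif),
      mean_effect = as.list(report$validation$diagnostics$mean_effect)),
    warning_leverage = report$validation$warning_leverage,
    domain = report$validation$domain,
    criteria = report$validation$criteria,
    screening = if (!is.null(report$screening)) list(
      n_passing = report$screening$n_passing,
      n_failing = report$screening$n_failing))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Recompute the published study's headline numbers from the fixtures
#'
#' Re-derives, from the packaged table transcriptions and printed model
#' equations, every statistic that the published tables make
#' recomputable: the validation-set predictions of Model 1 from the
#' printed descriptors, the external-validation sums of squares and
#' predictive R2 about the printed training mean, the warning leverage,
#' the adjusted R2 implied by the printed training R2, and the
#' rule-of-five screen of the 18 designed compounds. Returns
#' printed-versus-recomputed pairs with absolute differences.
#'
#' @param y_mintrn training-mean activity used by the published external
#'   validation (the printed value).
#' @param printed_r2 printed training R2 of Model 1.
#' @return list of class `reproduction_report`: `predictions`
#'   (per-compound recomputed vs printed), `statistics` (data.frame of
#'   printed vs recomputed headline numbers), `screening` summary.
#' @export
reproduce_paper_tables <- function(y_mintrn = 4.5364, printed_r2 = 0.6981) {
  t3 <- utils::read.csv(qsarlab_example("table3_external_validation.csv"))
  model1 <- published_model(1)
  X3 <- as.matrix(t3[, model1$descriptors])
  rownames(X3) <- t3$compound_id
  pred <- predict(model1, X3)
  predictions <- data.frame(
    compound_id = t3$compound_id,
    pic50_obs = t3$pic50_obs,
    pred_recomputed = as.numeric(pred),
    pred_printed = t3$pic50_pred_printed,
    abs_diff = abs(as.numeric(pred) - t3$pic50_pred_printed))

  # external validation from the printed observed/predicted columns
  ext <- external_r2pred(t3$pic50_obs, t3$pic50_pred_printed, y_mintrn)
  h_star <- warning_leverage(k = length(model1$descriptors), n = 27)
  r2_adj <- adjusted_r2(printed_r2, n = 27, p = length(model1$descriptors))

  props <- read_property_table(qsarlab_example("table10_properties.csv"))
  screen <- screen_table(props)

  statistics <- data.frame(
    quantity = c("SSres (external)", "SStot (external)", "R2pred",
                 "warning leverage h*", "adjusted R2"),
    printed = c(0.713008, 1.535707, 0.5357, 0.56, 0.6433),
    recomputed = c(ext$ss_res, ext$ss_tot, ext$r2_pred,
                   round(h_star, 2), r2_adj))
  statistics$abs_diff <- abs(statistics$printed - statistics$recomputed)

  structure(list(predictions = predictions, statistics = statistics,
                 screening = screen,
                 external = ext, warning_leverage = h_star,
                 adjusted_r2 = r2_adj),
            class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction of the published tables\n\n")
  cat("Model 1 validation-set predictions (recomputed vs printed):\n")
  print(x$predictions, digits = 5, row.names = FALSE)
  cat("\nHeadline statistics:\n")
  print(x$statistics, digits = 6, row.names = FALSE)
  cat(sprintf("\nRule-of-five screen of the designed compounds: %d/%d pass, %d with >= 2 violations\n",
              x$screening$n_passing, nrow(x$screening$table),
              x$screening$n_failing))
  invisible(x)
}

#' Verify the packaged fixture checksums
#'
#' @return data.frame of fixture files, their MD5 sums and whether each
#'   matches the recorded manifest.
#' @export
check_fixture_manifest <- function() {
  manifest <- jsonlite::read_json(qsarlab_example("fixture_manifest.json"),
                                  simplifyVector = TRUE)
  files <- names(manifest)
  sums <- vapply(files, function(f) unname(tools::md5sum(qsarlab_example(f))),
                 character(1))
  data.frame(file = files, md5 = sums,
             ok = sums == unlist(manifest), row.names = NULL)
}
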