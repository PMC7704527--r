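#' Construct a linear QSAR model
#'
#' A fitted (or published) multiple linear regression over named
#' molecular descriptors: pIC50 = intercept + sum_j beta_j * descriptor_j.
#'
#' @param descriptors character vector of descriptor names, in model order.
#' @param coefficients numeric vector, one coefficient per descriptor.
#' @param intercept numeric scalar.
#' @param name optional model label.
#' @return object of class `qsar_model`.
#' @export
qsar_model <- function(descriptors, coefficients, intercept, name = NULL) {
  if (length(descriptors) != length(coefficients)) {
    stop("one coefficient per descriptor required", call. = FALSE)
  }
  if (length(descriptors) == 0) stop("model needs at least one descriptor",
                                     call. = FALSE)
  if (anyDuplicated(descriptors)) stop("duplicate descriptor names in model",
                                       call. = FALSE)
  coefficients <- as.numeric(coefficients)
  intercept <- as.numeric(intercept)
  if (any(!is.finite(c(coefficients, intercept)))) {
    stop("model coefficients must be finite", call. = FALSE)
  }
  structure(list(descriptors = as.character(descriptors),
                 coefficients = coefficients,
                 intercept = intercept,
                 name = name),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, digits = 6, ...) {
  terms <- sprintf("%+.*g*%s", digits, x$coefficients, x$descriptors)
  cat(if (is.null(x$name)) "QSAR model" else x$name, "\n")
  cat("  pIC50 =", paste(terms, collapse = " "),
      sprintf("%+.*g", digits, x$intercept), "\n")
  invisible(x)
}

#' Predict activities from a linear QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata numeric matrix or data.frame whose columns include every
#'   model descriptor (matched by name; extra columns ignored).
#' @param ... unused.
#' @return named numeric vector of predicted activities, one per row of
#'   `newdata`, in row order.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.matrix(newdata)) {
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  }
  missing <- setdiff(object$descriptors, colnames(newdata))
  if (length(missing) > 0) {
    stop(sprintf("descriptor(s) missing from prediction data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  Xs <- newdata[, object$descriptors, drop = FALSE]
  storage.mode(Xs) <- "double"
  drop(Xs %*% object$coefficients) + object$intercept
}

#' Write a model to JSON
#'
#' Coefficients are serialized with full double precision (at least 12
#' significant digits survive a round-trip).
#'
#' @param model a `qsar_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(name = model$name, descriptors = model$descriptors,
              coefficients = model$coefficients, intercept = model$intercept)
  # 17 significant digits: doubles round-trip exactly through the text form
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path path to a model JSON file with fields `descriptors`,
#'   `coefficients`, `intercept` and optionally `name`.
#' @return a `qsar_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("descriptors", "coefficients", "intercept")) {
    if (is.null(obj[[f]])) stop("model JSON missing field: ", f, call. = FALSE)
  }
  qsar_model(obj$descriptors, obj$coefficients, obj$intercept,
             name = obj$name)
}
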