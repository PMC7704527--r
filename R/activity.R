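#' Convert IC50 (micromolar) to pIC50
#'
#' Activities measured as half-maximal inhibitory concentrations in
#' micromolar are converted to the negative base-10 logarithm of the molar
#' concentration: pIC50 = -log10(IC50 * 1e-6) = 6 - log10(IC50).
#'
#' @param ic50 numeric vector of IC50 values in micromolar; all strictly
#'   positive and finite.
#' @return numeric vector of pIC50 values (unitless).
#' @examples
#' ic50_to_pic50(c(1, 10))   # 6, 5
#' @seealso [pic50_to_ic50()] for the inverse.
#' @export
ic50_to_pic50 <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0) {
    stop("'ic50' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(ic50) | ic50 <= 0
  if (any(bad)) {
    stop(sprintf("IC50 values must be finite and > 0 (offending positions: %s)",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  6 - log10(ic50)
}

#' Convert pIC50 back to IC50 (micromolar)
#'
#' @param pic50 numeric vector of pIC50 values.
#' @return numeric vector of IC50 values in micromolar.
#' @export
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50) || length(pic50) == 0) {
    stop("'pic50' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(pic50))) {
    stop("pIC50 values must be finite", call. = FALSE)
  }
  10^(6 - pic50)
}

#' Read a compound activity table
#'
#' Reads a CSV with one row per compound carrying at least a compound
#' identifier and one of IC50 (micromolar) or pIC50. Recognised column
#' names (case-insensitive): `compound_id`/`id`/`name`/`compound` for the
#' identifier, `ic50` and `pic50` for the activities. When only IC50 is
#' given, pIC50 is derived; when both are given they must agree with
#' pIC50 = 6 - log10(IC50) within `tol`.
#'
#' @param path path to a CSV file (header row, "." decimal separator).
#' @param tol tolerance for the IC50/pIC50 consistency check.
#' @return data.frame with columns `compound_id` (character), `ic50`,
#'   `pic50` (numeric; `ic50` may be NA when only pIC50 was supplied).
#' @export
read_compound_table <- function(path, tol = 1e-6) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (nrow(raw) == 0) stop("activity table is empty: ", path, call. = FALSE)
  lc <- tolower(names(raw))
  id_col <- which(lc %in% c("compound_id", "id", "name", "compound"))[1]
  ic_col <- which(lc == "ic50")[1]
  pic_col <- which(lc == "pic50")[1]
  if (is.na(id_col)) {
    stop("no compound identifier column found (expected one of compound_id/id/name/compound)",
         call. = FALSE)
  }
  if (is.na(ic_col) && is.na(pic_col)) {
    stop("activity table needs an 'ic50' and/or 'pic50' column", call. = FALSE)
  }
  ids <- raw[[id_col]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate compound id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }

  parse_num <- function(col_idx, what) {
    if (is.na(col_idx)) return(rep(NA_real_, nrow(raw)))
    txt <- raw[[col_idx]]
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("unparsable %s value '%s' at row %d", what, txt[bad[1]], bad[1]),
           call. = FALSE)
    }
    out[txt == ""] <- NA_real_
    out
  }
  ic50 <- parse_num(ic_col, "IC50")
  pic50 <- parse_num(pic_col, "pIC50")

  missing_both <- which(is.na(ic50) & is.na(pic50))
  if (length(missing_both) > 0) {
    stop(sprintf("row %d (%s): no activity given", missing_both[1],
                 ids[missing_both[1]]), call. = FALSE)
  }
  neg <- which(!is.na(ic50) & ic50 <= 0)
  if (length(neg) > 0) {
    stop(sprintf("row %d (%s): IC50 must be > 0", neg[1], ids[neg[1]]),
         call. = FALSE)
  }
  both <- which(!is.na(ic50) & !is.na(pic50))
  if (length(both) > 0) {
    diff <- abs(pic50[both] - ic50_to_pic50(ic50[both]))
    off <- both[diff > tol]
    if (length(off) > 0) {
      stop(sprintf(
        "row %d (%s): IC50 %g and pIC50 %g are inconsistent (expected pIC50 %.6f)",
        off[1], ids[off[1]], ic50[off[1]], pic50[off[1]],
        ic50_to_pic50(ic50[off[1]])), call. = FALSE)
    }
  }
  fill <- is.na(pic50)
  if (any(fill)) pic50[fill] <- ic50_to_pic50(ic50[fill])

  data.frame(compound_id = as.character(ids), ic50 = ic50, pic50 = pic50,
             stringsAsFactors = FALSE)
}
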