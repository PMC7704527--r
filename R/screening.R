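#' Published QSAR model registry
#'
#' Returns one of the four published multiple-linear-regression
#' equations for the anti-proliferative imidazolone series, with
#' coefficients stored to full printed precision. Model 1 (MATS4e,
#' GATS5e, SpMax4_Bhs, RDF150u) is the equation selected by the original
#' validation study.
#'
#' @param model_id integer 1..4.
#' @return a [qsar_model()].
#' @examples
#' m1 <- published_model(1)
#' m1$intercept  # 13.256220911
#' @export
published_model <- function(model_id) {
  if (!is.numeric(model_id) || length(model_id) != 1 ||
      !(model_id %in% 1:4)) {
    stop("model_id must be 1, 2, 3 or 4", call. = FALSE)
  }
  path <- system.file("extdata", "published_models.json", package = "qsarlab",
                      mustWork = TRUE)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  entry <- reg[[paste0("model_", as.integer(model_id))]]
  qsar_model(entry$descriptors, entry$coefficients, entry$intercept,
             name = entry$name)
}

#' Read a physicochemical property table
#'
#' CSV with one row per compound; the first column is the compound
#' identifier and the remaining columns physicochemical properties named
#' by the usual abbreviations (MW, nAH, nRB, HBA, HBD, MR, TPSA, iLOGP,
#' optionally XLOGP3, ESOL_logS, Fsp3, ...). Annotation columns (e.g.
#' BBB, PAINS, Brenk) are carried through untouched.
#'
#' @param path CSV path.
#' @return data.frame with `compound_id` first and properties parsed
#'   numeric where possible.
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("property table is empty: ", path, call. = FALSE)
  names(df)[1] <- "compound_id"
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound ids in property table", call. = FALSE)
  }
  df
}

#' Lipinski rule-of-five check
#'
#' Violations: MW > 500, logP > 5, HBD > 5, HBA > 10 (all strict). A
#' compound passes (is considered orally available) when it has at most
#' one violation.
#'
#' @param mw molecular weight, g/mol.
#' @param logp octanol/water partition coefficient (e.g. iLOGP or ALogP).
#' @param hbd hydrogen-bond donor count.
#' @param hba hydrogen-bond acceptor count.
#' @param thresholds named list overriding the cutoffs `mw`, `logp`,
#'   `hbd`, `hba`.
#' @return list of class `rule_of_five`: `violations` (character vector
#'   naming the violated rules), `n_violations`, `passes`.
#' @export
lipinski_violations <- function(mw, logp, hbd, hba,
                                thresholds = list(mw = 500, logp = 5,
                                                  hbd = 5, hba = 10)) {
  vals <- list(mw = mw, logp = logp, hbd = hbd, hba = hba)
  for (nm in names(vals)) {
    if (is.null(vals[[nm]]) || length(vals[[nm]]) != 1 || is.na(vals[[nm]])) {
      stop(sprintf("missing property: %s", nm), call. = FALSE)
    }
  }
  v <- character(0)
  if (mw > thresholds$mw) v <- c(v, sprintf("MW>%g", thresholds$mw))
  if (logp > thresholds$logp) v <- c(v, sprintf("logP>%g", thresholds$logp))
  if (hbd > thresholds$hbd) v <- c(v, sprintf("HBD>%g", thresholds$hbd))
  if (hba > thresholds$hba) v <- c(v, sprintf("HBA>%g", thresholds$hba))
  structure(list(violations = v, n_violations = length(v),
                 passes = length(v) <= 1),
            class = "rule_of_five")
}

#' Default bioavailability-radar ranges
#'
#' The six-axis oral-bioavailability property window: lipophilicity
#' XLOGP3 in \[-0.7, 5.0\], size MW in \[150, 500\] g/mol, polarity TPSA in
#' \[20, 130\] A^2, solubility log S >= -6, saturation fraction of sp3
#' carbons >= 0.25, flexibility fewer than 9 rotatable bonds.
#'
#' @return named list of per-axis bounds.
#' @export
radar_ranges <- function() {
  list(lipophilicity = c(-0.7, 5.0),   # XLOGP3
       size = c(150, 500),             # MW, g/mol
       polarity = c(20, 130),          # TPSA, A^2
       solubility_min = -6,            # ESOL log S
       saturation_min = 0.25,          # fraction Csp3
       flexibility_max = 9)            # rotatable bonds, strict <
}

#' Bioavailability-radar range check
#'
#' Tests each radar axis against its property window (inclusive bounds,
#' except flexibility which requires strictly fewer than the maximum
#' rotatable bonds). Axes whose property is absent are reported as NA
#' ("not evaluated") and do not block `all_in_range`.
#'
#' @param profile named list or one-row data.frame with any of `XLOGP3`,
#'   `MW`, `TPSA`, `ESOL_logS`, `Fsp3`, `nRB`.
#' @param ranges axis bounds, see [radar_ranges()].
#' @return list of class `radar_result`: logical per-axis verdicts (NA =
#'   not evaluated) and `all_in_range`.
#' @export
radar_check <- function(profile, ranges = radar_ranges()) {
  if (is.data.frame(profile)) profile <- as.list(profile[1, , drop = FALSE])
  get <- function(nm) {
    v <- profile[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }
  in_range <- function(v, lo, hi) if (is.na(v)) NA else v >= lo & v <= hi
  xlogp3 <- get("XLOGP3"); mw <- get("MW"); tpsa <- get("TPSA")
  logs <- get("ESOL_logS"); fsp3 <- get("Fsp3"); nrb <- get("nRB")
  axes <- list(
    lipophilicity = in_range(xlogp3, ranges$lipophilicity[1], ranges$lipophilicity[2]),
    size = in_range(mw, ranges$size[1], ranges$size[2]),
    polarity = in_range(tpsa, ranges$polarity[1], ranges$polarity[2]),
    solubility = if (is.na(logs)) NA else logs >= ranges$solubility_min,
    saturation = if (is.na(fsp3)) NA else fsp3 >= ranges$saturation_min,
    flexibility = if (is.na(nrb)) NA else nrb < ranges$flexibility_max)
  evaluated <- !vapply(axes, is.na, logical(1))
  all_in <- if (!any(evaluated)) NA else all(unlist(axes[evaluated]))
  structure(c(axes, list(all_in_range = all_in)), class = "radar_result")
}

#' Screen a property table for drug-likeness
#'
#' Runs the Lipinski rule-of-five (and, where the properties are present,
#' the bioavailability-radar ranges) over every compound of a property
#' table.
#'
#' @param profiles data.frame as returned by [read_property_table()];
#'   needs MW, a logP column (`iLOGP`, `ALogP` or `logP`), HBA and HBD.
#' @param thresholds rule-of-five cutoffs, see [lipinski_violations()].
#' @return list of class `screen_summary`: `table` (per-compound
#'   verdicts), `n_passing` (at most one violation), `n_failing` (two or
#'   more violations).
#' @export
screen_table <- function(profiles,
                         thresholds = list(mw = 500, logp = 5,
                                           hbd = 5, hba = 10)) {
  if (nrow(profiles) == 0) stop("no compounds to screen", call. = FALSE)
  logp_col <- intersect(c("iLOGP", "ALogP", "logP", "XLOGP3"),
                        names(profiles))[1]
  for (col in c("MW", "HBA", "HBD")) {
    if (!col %in% names(profiles)) {
      stop(sprintf("missing property column: %s", col), call. = FALSE)
    }
  }
  if (is.na(logp_col)) stop("missing logP column (iLOGP/ALogP/logP/XLOGP3)",
                            call. = FALSE)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    r5 <- lipinski_violations(profiles$MW[i], profiles[[logp_col]][i],
                              profiles$HBD[i], profiles$HBA[i],
                              thresholds = thresholds)
    radar <- radar_check(profiles[i, , drop = FALSE])
    data.frame(compound_id = profiles$compound_id[i],
               n_violations = r5$n_violations,
               violations = paste(r5$violations, collapse = ";"),
               ro5_pass = r5$passes,
               radar_all_in_range = radar$all_in_range,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 n_passing = sum(tab$ro5_pass),
                 n_failing = sum(!tab$ro5_pass)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Drug-likeness screen: %d compounds, %d pass the rule of five, %d fail (>= 2 violations)\n",
              nrow(x$table), x$n_passing, x$n_failing))
  invisible(x)
}
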