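# Table validation and reference-range flagging.

#' Validate a concentration table against the panel schema
#'
#' Problems are reported, never raised: negative concentrations are errors,
#' columns outside the schema are warnings, and per-analyte missing counts
#' are tallied. Validation is idempotent.
#'
#' @param table a \code{sample_table}.
#' @param schema a \code{panel_schema}.
#' @return A \code{validation_report}: list with \code{errors} and
#'   \code{warnings} data frames (sample, analyte, message), \code{n_missing}
#'   and \code{passed} (\code{TRUE} iff no errors).
#' @export
validate_panel <- function(table, schema = panel_schema()) {
  empty <- data.frame(sample = character(), analyte = character(),
                      message = character(), stringsAsFactors = FALSE)
  errors <- empty
  warnings <- empty
  conc <- table$conc
  neg <- which(!is.na(conc) & conc < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    errors <- rbind(errors, data.frame(
      sample = rownames(conc)[neg[, 1]],
      analyte = colnames(conc)[neg[, 2]],
      message = "negative concentration", stringsAsFactors = FALSE))
  }
  extra <- setdiff(colnames(conc), schema$metabolite_names)
  if (length(extra)) {
    warnings <- rbind(warnings, data.frame(
      sample = NA_character_, analyte = extra,
      message = "column not in schema", stringsAsFactors = FALSE))
  }
  structure(
    list(errors = errors, warnings = warnings,
         n_missing = sum(is.na(conc)),
         missing_by_analyte = colSums(is.na(conc)),
         passed = nrow(errors) == 0L),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> passed:", x$passed,
      "| errors:", nrow(x$errors), "| warnings:", nrow(x$warnings),
      "| missing cells:", x$n_missing, "\n")
  invisible(x)
}

#' Printed plasma reference values
#'
#' The reference constants used for flagging: mean control glutamine 800
#' micromol/L, normal glutamate 40 micromol/L, normal aspartate 0-5
#' micromol/L, normal phenylalanine 40-74 micromol/L, and the
#' lactate/pyruvate upper normal of 25.8 above which oxidative
#' phosphorylation deficiency is suspected.
#'
#' @return A named list of reference values.
#' @export
reference_ranges <- function() {
  list(
    gln_normal_mean = 800,
    glu_normal = 40,
    asp_normal_range = c(0, 5),
    phe_normal_range = c(40, 74),
    lac_pyr_upper_normal = 25.8
  )
}

#' Flag samples against reference ranges
#'
#' Deterministic per-sample screening flags: \code{oxphos_deficiency}
#' (Lac/Pyr > 25.8), \code{hyperphenylalaninemia} (Phe above 74),
#' \code{hypoglutaminemia} (Gln below half the 800 control mean),
#' \code{hyperglutamatemia} (Glu above 40) and \code{hyperaspartatemia}
#' (Asp above 5). A flag whose analytes are absent from the table is skipped
#' with a warning; a zero or missing denominator yields \code{NA}
#' (indeterminate), never a crash.
#'
#' @param table a \code{sample_table}.
#' @param ranges output of \code{\link{reference_ranges}}.
#' @return Data frame with \code{sample_id} and one logical column per flag
#'   computed (\code{NA} = indeterminate).
#' @export
reference_flags <- function(table, ranges = reference_ranges()) {
  conc <- table$conc
  get <- function(a) if (a %in% colnames(conc)) conc[, a] else NULL
  out <- data.frame(sample_id = table$sample_id, stringsAsFactors = FALSE)
  lac <- get("Lac"); pyr <- get("Pyr")
  if (is.null(lac) || is.null(pyr)) {
    warning("Lac and/or Pyr absent; oxphos_deficiency flag skipped",
            call. = FALSE)
  } else {
    ratio <- ifelse(is.na(pyr) | pyr == 0, NA_real_, lac / pyr)
    out$oxphos_deficiency <- ratio > ranges$lac_pyr_upper_normal
  }
  phe <- get("Phe")
  if (is.null(phe)) {
    warning("Phe absent; hyperphenylalaninemia flag skipped", call. = FALSE)
  } else {
    out$hyperphenylalaninemia <- phe > ranges$phe_normal_range[2]
  }
  gln <- get("Gln")
  if (is.null(gln)) {
    warning("Gln absent; hypoglutaminemia flag skipped", call. = FALSE)
  } else {
    out$hypoglutaminemia <- gln < ranges$gln_normal_mean / 2
  }
  glu <- get("Glu")
  if (!is.null(glu)) out$hyperglutamatemia <- glu > ranges$glu_normal
  asp <- get("Asp")
  if (!is.null(asp)) out$hyperaspartatemia <- asp > ranges$asp_normal_range[2]
  out
}
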