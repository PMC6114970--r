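# Concentration-table container and delimited I/O with dialect-tolerant
# header normalization.

#' Sample-by-metabolite concentration table
#'
#' Container for a cohort of plasma samples quantified on the panel:
#' a numeric matrix of concentrations (micromol/L, rows = samples, columns =
#' analytes, \code{NA} = missing/below-LOD-masked), a group label per sample
#' and optional free-form metadata.
#'
#' @param conc numeric matrix, rows samples, columns canonical analyte names.
#' @param group character vector of group labels, recycled if length 1.
#' @param sample_id unique sample identifiers; defaults to rownames or S1..Sn.
#' @param metadata optional named list of per-sample vectors.
#' @return An object of class \code{sample_table}.
#' @export
sample_table <- function(conc, group = "unspecified", sample_id = NULL,
                         metadata = list()) {
  conc <- as.matrix(conc)
  storage.mode(conc) <- "double"
  n <- nrow(conc)
  if (is.null(sample_id)) {
    sample_id <- rownames(conc)
    if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  }
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_ids", call. = FALSE)
  if (length(group) == 1L) group <- rep(group, n)
  stopifnot(length(group) == n, length(sample_id) == n)
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  rownames(conc) <- sample_id
  structure(
    list(sample_id = sample_id, group = as.character(group), conc = conc,
         metadata = metadata),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x$conc), " samples x ", ncol(x$conc),
      " analytes; groups: ",
      paste(names(table(x$group)), table(x$group), sep = ":", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$conc)

#' @export
as.data.frame.sample_table <- function(x, ...) {
  data.frame(sample_id = x$sample_id, group = x$group,
             as.data.frame(x$conc, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}

# Collapse a header to a dialect-free key: case and every separator
# (space, dot, underscore, colon, dash, parentheses) are ignored.
.name_key <- function(x) tolower(gsub("[^0-9a-zA-Z]", "", x))

# Common aliases seen in exports of this panel and in the literature.
.NAME_ALIASES <- c(
  tau = "Taurine", h1 = "Hexoses", hexose = "Hexoses", glucose = "Hexoses",
  lactate = "Lac", pyruvate = "Pyr", pyruvateoxaloacetate = "Pyr",
  fumarate = "Fum", succinate = "Suc",
  alphaketoglutarate = "alpha-KG", akg = "alpha-KG",
  xle = "Xle"
)

#' Map analyte-column dialects to canonical panel names
#'
#' Accepts the canonical names plus dotted (\code{PC.aa.C36.6}), underscored
#' and other separator dialects produced by vendor exports, and a small alias
#' table (\code{Tau}, \code{H1}, \code{Lactate}, ...). Unrecognized names are
#' returned as \code{NA}.
#'
#' @param x character vector of column headers.
#' @param schema a \code{panel_schema}.
#' @return Character vector of canonical names with \code{NA} for unknowns.
#' @export
normalize_analyte_names <- function(x, schema = panel_schema()) {
  canon <- schema$metabolite_names
  lut <- stats::setNames(canon, .name_key(canon))
  ali <- .NAME_ALIASES[.name_key(.NAME_ALIASES) %in% names(lut) |
                         .NAME_ALIASES %in% canon]
  lut <- c(lut, stats::setNames(as.character(ali), names(ali)))
  out <- lut[.name_key(x)]
  unname(out)
}

#' Write a sample table to a delimited file
#'
#' Columns are \code{sample_id}, \code{group}, then analytes in schema order
#' (restricted to those present). Missing values are written as empty cells.
#'
#' @param table a \code{sample_table}.
#' @param path output path; extension \code{.csv} selects comma, anything
#'   else tab separation.
#' @return \code{path}, invisibly.
#' @export
write_panel_table <- function(table, path) {
  df <- as.data.frame(table)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a delimited concentration table
#'
#' Reads a CSV/TSV with a header row of analyte names (any supported
#' dialect) plus the reserved columns \code{sample_id} and \code{group}.
#' Analyte headers are normalized to canonical panel names; unknown columns
#' are dropped with a warning. Empty cells become missing values. Zeros are
#' treated according to the below-LOD policy: \code{"half_min"} (default)
#' replaces them by half the smallest positive value observed for that
#' analyte, \code{"missing"} masks them, \code{"keep"} leaves them.
#'
#' @param path input file.
#' @param schema a \code{panel_schema}.
#' @param lod_policy one of \code{"half_min"}, \code{"missing"}, \code{"keep"}.
#' @return A \code{sample_table}.
#' @export
load_panel_table <- function(path, schema = panel_schema(),
                             lod_policy = c("half_min", "missing", "keep")) {
  lod_policy <- match.arg(lod_policy)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          fileEncoding = "UTF-8", quote = "\"")
  hdr <- names(df)
  key <- .name_key(hdr)
  id_col <- match("sampleid", key)
  grp_col <- match("group", key)
  meta_idx <- c(id_col, grp_col)
  meta_idx <- meta_idx[!is.na(meta_idx)]
  canon <- normalize_analyte_names(hdr, schema)
  canon[meta_idx] <- NA
  unknown <- setdiff(which(is.na(canon)), meta_idx)
  if (length(unknown)) {
    warning("dropping unrecognized columns: ",
            paste(hdr[unknown], collapse = ", "), call. = FALSE)
  }
  keep <- which(!is.na(canon))
  if (!length(keep)) stop("no recognizable analyte columns", call. = FALSE)
  conc <- as.matrix(df[, keep, drop = FALSE])
  storage.mode(conc) <- "double"
  colnames(conc) <- canon[keep]
  if (anyDuplicated(colnames(conc))) {
    stop("duplicate analyte columns after normalization", call. = FALSE)
  }
  conc <- apply_lod_policy(conc, lod_policy)
  sample_id <- if (!is.na(id_col)) as.character(df[[id_col]]) else NULL
  group <- if (!is.na(grp_col)) as.character(df[[grp_col]]) else "unspecified"
  sample_table(conc, group = group, sample_id = sample_id)
}

#' Apply the below-LOD zero policy to a concentration matrix
#'
#' @param conc numeric matrix.
#' @param policy \code{"half_min"}, \code{"missing"} or \code{"keep"}.
#' @return The matrix with zeros handled per policy.
#' @export
apply_lod_policy <- function(conc, policy = c("half_min", "missing", "keep")) {
  policy <- match.arg(policy)
  if (policy == "keep") return(conc)
  for (j in seq_len(ncol(conc))) {
    z <- which(!is.na(conc[, j]) & conc[, j] == 0)
    if (!length(z)) next
    if (policy == "missing") {
      conc[z, j] <- NA_real_
    } else {
      pos <- conc[, j][!is.na(conc[, j]) & conc[, j] > 0]
      conc[z, j] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
  }
  conc
}
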