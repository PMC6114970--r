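# Declarative catalog of the metabolite sums, quotients and composite
# equations used as biochemical-function proxies, with an evaluator that
# propagates missingness and never divides by zero.

# --- expression trees -------------------------------------------------------
# A ratio expression is a nested list: leaf (analyte symbol), sum of
# sub-expressions, or quotient of two sub-expressions.

r_leaf <- function(name) list(op = "leaf", name = name)

r_sum <- function(...) {
  args <- lapply(list(...), .as_expr)
  list(op = "sum", args = args)
}

r_div <- function(num, den) {
  list(op = "div", num = .as_expr(num), den = .as_expr(den))
}

.as_expr <- function(x) {
  if (is.character(x)) r_leaf(x) else x
}

.expr_leaves <- function(e) {
  switch(e$op,
    leaf = e$name,
    sum = unlist(lapply(e$args, .expr_leaves)),
    div = c(.expr_leaves(e$num), .expr_leaves(e$den))
  )
}

.expr_string <- function(e) {
  switch(e$op,
    leaf = e$name,
    sum = paste0("(", paste(vapply(e$args, .expr_string, ""),
                            collapse = " + "), ")"),
    div = paste0("(", .expr_string(e$num), " / ", .expr_string(e$den), ")")
  )
}

# Net concentration degree of an expression (sums: degree of terms, which
# must agree; quotient: num - den). Used by scale-invariance tests.
.expr_degree <- function(e) {
  switch(e$op,
    leaf = 1,
    sum = .expr_degree(e$args[[1]]),
    div = .expr_degree(e$num) - .expr_degree(e$den)
  )
}

#' Evaluate a ratio definition on one sample
#'
#' Recursively evaluates the expression tree against a named concentration
#' vector. A missing leaf or a zero denominator makes the value missing with
#' the reason recorded in the \code{"reason"} attribute; the result is never
#' infinite.
#'
#' @param defn a \code{ratio_definition} (an element of a catalog).
#' @param sample named numeric vector of concentrations.
#' @return A numeric scalar, possibly \code{NA} with a \code{reason}
#'   attribute.
#' @export
evaluate_expression <- function(defn, sample) {
  ev <- function(e) {
    switch(e$op,
      leaf = {
        v <- sample[e$name]
        if (is.null(v) || length(v) == 0 || is.na(v)) {
          structure(NA_real_, reason = paste0("missing leaf: ", e$name))
        } else as.numeric(v)
      },
      sum = {
        vals <- lapply(e$args, ev)
        bad <- vapply(vals, is.na, logical(1))
        if (any(bad)) vals[[which(bad)[1]]] else sum(unlist(vals))
      },
      div = {
        num <- ev(e$num); den <- ev(e$den)
        if (is.na(num)) num
        else if (is.na(den)) den
        else if (den == 0) structure(NA_real_, reason = "zero denominator")
        else num / den
      }
    )
  }
  ev(defn$expression)
}

.ratio_definition <- function(name, expression, category,
                              direction = "unknown", anchor = "") {
  structure(
    list(name = name, expression = expression, category = category,
         direction_in_case = direction, anchor = anchor),
    class = "ratio_definition"
  )
}

# --- default catalog --------------------------------------------------------

#' Build the default ratio catalog
#'
#' Assembles every sum, quotient, enzyme-activity proxy and composite
#' equation of the panel's ratio vocabulary: amino-acid family sums,
#' acylcarnitine and structural-lipid sums, desaturase and elongase proxies,
#' Fischer's quotient and its variants, inborn-error screening ratios,
#' fatty-acid-oxidation (VLCAD/CPT-2) ratios, oxidative-stress and arginine
#' methylation markers, glutaminolysis/MYC proxies including the
#' ornithine-decarboxylase panel and the glutamate pulling-effect composites,
#' glycolysis (PHGDH, GCKR) proxies, glycolysis/glutaminolysis balance
#' equations, hexose composites, the saturated/monounsaturated acyl-alkyl PC
#' discriminant, and the two-feature breast-cancer signature equation.
#'
#' Entries whose leaves are absent from \code{schema} (e.g. energy
#' metabolites on a core-only schema) are retained but marked unavailable.
#'
#' @param schema a \code{panel_schema}.
#' @return An object of class \code{ratio_catalog}.
#' @examples
#' cat186 <- build_default_catalog(panel_schema())
#' length(cat186$definitions)
#' @export
build_default_catalog <- function(schema = panel_schema()) {
  defs <- list()
  add <- function(name, expr, category, direction = "unknown", anchor = "") {
    defs[[length(defs) + 1L]] <<-
      .ratio_definition(name, .as_expr(expr), category, direction, anchor)
  }
  S <- function(nms) do.call(r_sum, as.list(nms))

  aa <- .AA_NAMES
  ess <- .ESSENTIAL_AA
  add("Essential AA", S(ess), "aa_sum")
  add("Non-essential AA", S(setdiff(aa, ess)), "aa_sum")
  add("Gluc AA", S(c("Ala", "Gly", "Ser")), "aa_sum")
  add("BCAA", S(c("Leu", "Ile", "Val")), "aa_sum")
  add("Arom AA", S(c("His", "Tyr", "Trp", "Phe")), "aa_sum")
  add("Ala+Asp+Glu", S(c("Ala", "Asp", "Glu")), "aa_sum", "up")
  add("Total AA", S(aa), "aa_sum")

  add("Total AC", S(.AC_NAMES), "ac_sum")
  add("C2+C3", S(c("C2", "C3")), "ac_sum")
  add("C16+C18", S(c("C16", "C18")), "ac_sum", "up")
  add("C16+C18:1", S(c("C16", "C18:1")), "ac_sum", "up")
  add("C16-OH+C18:1-OH", S(c("C16-OH", "C18:1-OH")), "ac_sum")

  add("Total LPC", S(.LPC_NAMES), "lipid_sum")
  add("Total PC aa", S(.PC_AA_NAMES), "lipid_sum")
  add("Total PC ae", S(.PC_AE_NAMES), "lipid_sum")
  add("Total SM", S(.SM_NAMES), "lipid_sum")
  add("Structural lipids",
      S(c(.LPC_NAMES, .PC_AA_NAMES, .PC_AE_NAMES, .SM_NAMES)), "lipid_sum")
  add("Structural lipids/Gln",
      r_div(S(c(.LPC_NAMES, .PC_AA_NAMES, .PC_AE_NAMES, .SM_NAMES)), "Gln"),
      "myc_proxy", "up")
  add("Structural lipids/Hexoses",
      r_div(S(c(.LPC_NAMES, .PC_AA_NAMES, .PC_AE_NAMES, .SM_NAMES)),
            "Hexoses"),
      "myc_proxy", "up")

  add("Desaturase 9",
      r_div(S(c("PC ae C36:1", "PC ae C38:1", "PC ae C42:1")), "PC ae C42:0"),
      "desaturase")
  add("Desaturase 6",
      r_div(S(c("PC ae C44:6", "PC ae C44:5", "PC ae C42:5", "PC ae C40:6",
                "PC ae C40:5", "PC ae C38:6", "PC ae C38:5", "PC ae C36:5")),
            S(c("PC ae C36:1", "PC ae C38:1", "PC ae C42:1"))),
      "desaturase")

  add("Fischer", r_div(S(c("Leu", "Ile", "Val")), S(c("Tyr", "Phe"))),
      "liver", "down")
  add("Val/Phe", r_div("Val", "Phe"), "liver", "down")
  add("Xle/Phe", r_div(S(c("Leu", "Ile")), "Phe"), "liver", "down")

  add("C5/C4", r_div("C5", "C4"), "iem")
  add("Tyr/Ser", r_div("Tyr", "Ser"), "iem")
  add("Gly/Ala", r_div("Gly", "Ala"), "iem")
  add("Gly/Gln", r_div("Gly", "Gln"), "iem")
  add("Lac/Pyr", r_div("Lac", "Pyr"), "iem", "up")

  cpt2 <- r_div(S(c("C16", "C18:1")), "C2")
  add("CPT2 (C16+C18:1)/C2", cpt2, "faod")
  add("C14:1/C4", r_div("C14:1", "C4"), "faod")
  add("C14:1-OH/C9", r_div("C14:1-OH", "C9"), "faod", "up")
  add("C14/C9", r_div("C14", "C9"), "faod")
  add("C14:1/C9", r_div("C14:1", "C9"), "faod")
  add("C16/C3", r_div("C16", "C3"), "faod", "up")
  add("ELOVL2", r_div("PC aa C40:3", "PC aa C42:5"), "faod")

  add("Met-SO", r_leaf("Met-SO"), "oxidative", "up")
  add("Met-SO/Met", r_div("Met-SO", "Met"), "oxidative", "up")
  add("ADMA", r_leaf("ADMA"), "oxidative")
  add("SDMA", r_leaf("SDMA"), "oxidative")
  tdma <- r_sum("ADMA", "SDMA")
  add("Total DMA", tdma, "oxidative", "up")
  add("ADMA/Arg", r_div("ADMA", "Arg"), "oxidative")
  add("SDMA/Arg", r_div("SDMA", "Arg"), "oxidative")
  add("Total DMA/Arg", r_div(tdma, "Arg"), "oxidative")

  gln_glu <- r_div("Gln", "Glu")
  gga <- r_div(gln_glu, "Asp")        # (Gln/Glu)/Asp
  add("Gln/Glu", gln_glu, "myc_proxy", "down")
  add("(Glu+Asp+Ala)/Gln", r_div(S(c("Glu", "Asp", "Ala")), "Gln"),
      "myc_proxy", "up")
  add("(Gln/Glu)/Asp", gga, "myc_proxy", "down")
  add("Glu/Hexoses", r_div("Glu", "Hexoses"), "myc_proxy", "up")
  # Murine "Glucose" ratios map to the panel's hexoses channel.
  add("Hexoses/Ser", r_div("Hexoses", "Ser"), "myc_proxy", "down")
  add("Hexoses/Gly", r_div("Hexoses", "Gly"), "myc_proxy", "down")
  add("Hexoses/Ala", r_div("Hexoses", "Ala"), "myc_proxy", "down")

  add("Glu", r_leaf("Glu"), "myc_proxy", "up")
  add("Glu/Orn", r_div("Glu", "Orn"), "myc_proxy")
  add("Pro", r_leaf("Pro"), "myc_proxy")
  add("Pro/Orn", r_div("Pro", "Orn"), "myc_proxy")
  add("Orn", r_leaf("Orn"), "myc_proxy")
  add("Orn/Arg", r_div("Orn", "Arg"), "myc_proxy")
  add("Putrescine", r_leaf("Putrescine"), "myc_proxy")
  add("Putrescine/Orn", r_div("Putrescine", "Orn"), "myc_proxy")
  add("Spermidine", r_leaf("Spermidine"), "myc_proxy")
  add("Spermidine/Putrescine", r_div("Spermidine", "Putrescine"), "myc_proxy")
  add("Spermine", r_leaf("Spermine"), "myc_proxy")
  add("Spermine/Spermidine", r_div("Spermine", "Spermidine"), "myc_proxy")

  ala_glu <- r_div("Ala", "Glu")
  add("ALT (Ala/Glu)", ala_glu, "liver", "down")
  add("AST (Asp/Glu)", r_div("Asp", "Glu"), "liver")
  add("(Glu/Hexoses)/(Ala/Glu)", r_div(r_div("Glu", "Hexoses"), ala_glu),
      "myc_proxy", "up")
  add("((Glu/Gln)/Hexoses)/(Ala/Glu)",
      r_div(r_div(r_div("Glu", "Gln"), "Hexoses"), ala_glu),
      "myc_proxy", "up")

  ser_c2 <- r_div("Ser", "C2")
  add("Ser/C2", ser_c2, "glycolysis")
  add("Ser/Gln", r_div("Ser", "Gln"), "glycolysis", "up")
  add("Ser/Thr", r_div("Ser", "Thr"), "glycolysis")
  gckr1 <- r_div("PC aa C42:0", "PC ae C32:3")
  gckr2 <- r_div("PC aa C32:2", "PC ae C34:2")
  add("GCKR (PC aa C42:0/PC ae C32:3)", gckr1, "glycolysis")
  add("GCKR (PC aa C32:2/PC ae C34:2)", gckr2, "glycolysis")

  add("(Ser/C2)/(Gln/Glu)", r_div(ser_c2, gln_glu), "balance", "up")
  add("(Ser/C2)/((Gln/Glu)/Asp)", r_div(ser_c2, gga), "balance", "up")
  add("(PC aa C32:2/PC ae C34:2)/(Gln/Glu)", r_div(gckr2, gln_glu),
      "balance")
  add("(PC aa C32:2/PC ae C34:2)/((Gln/Glu)/Asp)", r_div(gckr2, gga),
      "balance")

  add("Hexoses/Lac", r_div("Hexoses", "Lac"), "oncometabolite", "down")
  add("Fum/Hexoses", r_div("Fum", "Hexoses"), "oncometabolite", "up")
  add("Suc/Hexoses", r_div("Suc", "Hexoses"), "oncometabolite", "up")
  add("Hexoses/(Ala+Gly+Ser)", r_div("Hexoses", S(c("Ala", "Gly", "Ser"))),
      "oncometabolite", "down")
  add("Hexoses/(C14:1/C4)", r_div("Hexoses", r_div("C14:1", "C4")),
      "oncometabolite", "down")
  add("Hexoses/(C18:1/C8)", r_div("Hexoses", r_div("C18:1", "C8")),
      "oncometabolite", "down")
  add("Hexoses/(C16/C3)", r_div("Hexoses", r_div("C16", "C3")),
      "oncometabolite", "down")
  add("Hexoses/CPT2", r_div("Hexoses", cpt2), "oncometabolite", "down")
  # PHGDH activity resolved to its first-listed proxy, Ser/C2.
  add("Hexoses/PHGDH", r_div("Hexoses", ser_c2), "oncometabolite", "down")
  # AcylC-DC read as the sum of dicarboxyl (-DC) acylcarnitines.
  dc <- .AC_NAMES[vapply(.AC_NAMES,
                         function(n) parse_metabolite_name(n)$dicarboxyl,
                         logical(1))]
  add("Hexoses/AcylC-DC", r_div("Hexoses", S(dc)), "oncometabolite", "down")
  add("Hexoses/lysoPC a C26:1", r_div("Hexoses", "lysoPC a C26:1"),
      "oncometabolite", "down")
  add("Hexoses/lysoPC a C28:1", r_div("Hexoses", "lysoPC a C28:1"),
      "oncometabolite", "down")

  # Saturated / monounsaturated acyl-alkyl PCs with more than 36 carbons,
  # membership derived mechanically from the name parser.
  ae_parsed <- lapply(.PC_AE_NAMES, parse_metabolite_name)
  big <- vapply(ae_parsed, function(p) p$carbons > 36, logical(1))
  sfa <- .PC_AE_NAMES[big & vapply(ae_parsed, function(p)
    p$double_bonds == 0, logical(1))]
  mufa <- .PC_AE_NAMES[big & vapply(ae_parsed, function(p)
    p$double_bonds == 1, logical(1))]
  add("SFA", S(sfa), "lipid_sum")
  add("MUFA", S(mufa), "lipid_sum")
  add("(SFA/MUFA)/(Asp/Gln)",
      r_div(r_div(S(sfa), S(mufa)), r_div("Asp", "Gln")),
      "discriminant", "down")

  add("Phe/((Gln/Glu)/Asp)", r_div("Phe", gga), "discriminant", "up")
  add("Total DMA/((Gln/Glu)/Asp)", r_div(tdma, gga), "discriminant", "up")
  add("Taurine/((Gln/Glu)/Asp)", r_div("Taurine", gga), "discriminant", "up")

  add("BC signature (Val/Phe)", .bc_signature_expr("val_phe"),
      "discriminant", "up")
  add("BC signature (Xle/Phe)", .bc_signature_expr("xle_phe"),
      "discriminant", "up")

  nms <- vapply(defs, `[[`, "", "name")
  stopifnot(!anyDuplicated(nms))
  available <- stats::setNames(
    vapply(defs, function(d)
      all(.expr_leaves(d$expression) %in% schema$metabolite_names),
      logical(1)),
    nms)
  if (any(!available)) {
    warning("catalog entries unavailable on this schema: ",
            paste(nms[!available], collapse = ", "), call. = FALSE)
  }
  structure(
    list(definitions = stats::setNames(defs, nms), available = available),
    class = "ratio_catalog"
  )
}

.bc_signature_expr <- function(variant = c("val_phe", "xle_phe")) {
  variant <- match.arg(variant)
  num_ratio <- if (variant == "val_phe") r_div("Val", "Phe")
               else r_div(r_sum("Leu", "Ile"), "Phe")
  r_div(r_div("PC aa C36:6", r_div(num_ratio, "Taurine")), "C10:2")
}

#' @export
print.ratio_catalog <- function(x, ...) {
  cat("<ratio_catalog> ", length(x$definitions), " definitions (",
      sum(x$available), " available)\n", sep = "")
  invisible(x)
}

#' Breast-cancer signature equation
#'
#' Evaluates the two quantities of the paper-style bivariate breast-cancer
#' discriminant for each sample: the composite equation
#' \code{\{PC aa C36:6 / [(Val/Phe)/Taurine]\} / C10:2} (or the Xle = Leu+Ile
#' variant) and the pass-through lipid \code{PC aa C28:1}. Increasing
#' signature values mark the case phenotype: cases show lower Val/Phe
#' (falling Fischer-type liver index), higher taurine and lower C10:2, all
#' of which raise the score.
#'
#' @param table a \code{sample_table} or a named numeric vector for one
#'   sample.
#' @param variant \code{"val_phe"} (default) or \code{"xle_phe"}.
#' @return Data frame with columns \code{signature} and \code{pc_aa_c28_1}.
#' @examples
#' x <- c("PC aa C36:6" = 1, Val = 220, Phe = 57, Taurine = 60,
#'        "C10:2" = 0.05, "PC aa C28:1" = 2)
#' bc_signature(x)
#' @export
bc_signature <- function(table, variant = c("val_phe", "xle_phe")) {
  variant <- match.arg(variant)
  defn <- .ratio_definition("bc_signature", .bc_signature_expr(variant),
                            "discriminant", "up")
  lipid <- .ratio_definition("PC aa C28:1", r_leaf("PC aa C28:1"),
                             "discriminant")
  rows <- if (inherits(table, "sample_table")) {
    lapply(seq_len(nrow(table$conc)), function(i) table$conc[i, ])
  } else list(table)
  data.frame(
    signature = vapply(rows, function(s)
      as.numeric(evaluate_expression(defn, s)), numeric(1)),
    pc_aa_c28_1 = vapply(rows, function(s)
      as.numeric(evaluate_expression(lipid, s)), numeric(1))
  )
}

#' Evaluate a catalog on a sample table
#'
#' Produces the feature table: one column per available catalog entry, one
#' row per sample, missingness propagated cell-wise. Evaluation is
#' deterministic and order-stable.
#'
#' @param table a \code{sample_table}.
#' @param catalog a \code{ratio_catalog}.
#' @param keep_analytes optionally append these raw analyte columns.
#' @return A \code{feature_table}: list with \code{sample_id}, \code{group}
#'   and numeric matrix \code{features}.
#' @export
evaluate_catalog <- function(table, catalog = build_default_catalog(),
                             keep_analytes = character()) {
  defs <- catalog$definitions[catalog$available]
  n <- nrow(table$conc)
  feat <- matrix(NA_real_, n, length(defs),
                 dimnames = list(table$sample_id, names(defs)))
  for (i in seq_len(n)) {
    s <- table$conc[i, ]
    feat[i, ] <- vapply(defs, function(d)
      as.numeric(evaluate_expression(d, s)), numeric(1))
  }
  if (length(keep_analytes)) {
    keep_analytes <- intersect(keep_analytes, colnames(table$conc))
    feat <- cbind(feat, table$conc[, keep_analytes, drop = FALSE])
  }
  feature_table(feat, group = table$group, sample_id = table$sample_id)
}

#' Feature table container
#'
#' @param features numeric matrix, rows samples, columns features.
#' @param group group label per sample.
#' @param sample_id sample identifiers.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(features, group, sample_id = rownames(features)) {
  features <- as.matrix(features)
  if (any(is.infinite(features))) {
    stop("feature values must be finite or missing", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(features)))
  rownames(features) <- sample_id
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group), features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " samples x ",
      ncol(x$features), " features\n", sep = "")
  invisible(x)
}

#' Export a ratio catalog as JSON
#'
#' @param catalog a \code{ratio_catalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_catalog_json <- function(catalog, path) {
  doc <- lapply(catalog$definitions, function(d) list(
    name = d$name,
    expression = .expr_string(d$expression),
    category = d$category,
    direction_in_case = d$direction_in_case,
    degree = .expr_degree(d$expression)
  ))
  jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
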