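# Canonical roster of the 186-analyte targeted plasma panel plus the optional
# energy-metabolite extension measured for the European samples.

.AC_NAMES <- c(
  "C0", "C2", "C3", "C3:1", "C3-OH",
  "C4", "C4:1", "C4-OH",
  "C5", "C5:1", "C5:1-DC", "C5-DC", "C5-M-DC", "C5-OH",
  "C6", "C6:1", "C7-DC",
  "C8", "C9",
  "C10", "C10:1", "C10:2",
  "C12", "C12:1", "C12-DC",
  "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH",
  "C16", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH", "C16-OH",
  "C18", "C18:1", "C18:1-OH", "C18:2"
)

.AA_NAMES <- c(
  "Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

.BA_NAMES <- c(
  "Ac-Orn", "ADMA", "alpha-AAA", "Carnosine", "Creatinine", "DOPA",
  "Dopamine", "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "PEA",
  "Putrescine", "Sarcosine", "SDMA", "Serotonin", "Spermidine", "Spermine",
  "Taurine"
)

.PC_AA_NAMES <- paste("PC aa", c(
  "C24:0", "C26:0", "C28:1", "C30:0", "C30:2",
  "C32:0", "C32:1", "C32:2", "C32:3",
  "C34:1", "C34:2", "C34:3", "C34:4",
  "C36:0", "C36:1", "C36:2", "C36:3", "C36:4", "C36:5", "C36:6",
  "C38:0", "C38:1", "C38:3", "C38:4", "C38:5", "C38:6",
  "C40:1", "C40:2", "C40:3", "C40:4", "C40:5", "C40:6",
  "C42:0", "C42:1", "C42:2", "C42:4", "C42:5", "C42:6"
))

.PC_AE_NAMES <- paste("PC ae", c(
  "C30:0", "C30:1", "C30:2",
  "C32:1", "C32:2", "C32:3",
  "C34:1", "C34:2", "C34:3",
  "C36:0", "C36:1", "C36:2", "C36:3", "C36:4", "C36:5",
  "C38:0", "C38:1", "C38:2", "C38:3", "C38:4", "C38:5", "C38:6",
  "C40:1", "C40:2", "C40:3", "C40:4", "C40:5", "C40:6",
  "C42:0", "C42:1", "C42:2", "C42:3", "C42:4", "C42:5",
  "C44:3", "C44:4", "C44:5", "C44:6"
))

.LPC_NAMES <- paste("lysoPC a", c(
  "C14:0", "C16:0", "C16:1", "C17:0", "C18:0", "C18:1", "C18:2",
  "C20:3", "C20:4", "C24:0", "C26:0", "C26:1", "C28:0", "C28:1"
))

.SM_NAMES <- c(
  paste("SM (OH)", c("C14:1", "C16:1", "C22:1", "C22:2", "C24:1")),
  paste("SM", c("C16:0", "C16:1", "C18:0", "C18:1", "C20:2", "C22:3",
                "C24:0", "C24:1", "C26:0", "C26:1"))
)

.ENERGY_NAMES <- c("Lac", "Pyr", "alpha-KG", "Fum", "Suc")

#' Panel schema for the 186-analyte targeted plasma metabolome
#'
#' Builds the canonical analyte roster of the p180-style panel: 40
#' acylcarnitines, 21 amino acids, 19 biogenic amines, the combined hexoses
#' channel, 38 diacyl and 38 acyl-alkyl phosphatidylcholines, 14
#' lyso-phosphatidylcholines and 15 sphingomyelins (186 analytes in total).
#' The optional energy extension adds lactate, the combined
#' pyruvate/oxaloacetate channel (named \code{Pyr}), alpha-ketoglutarate,
#' fumarate and succinate, which were quantified for a subset of cohorts
#' only. All concentrations are in micromol/L of plasma; there is no unit
#' conversion layer.
#'
#' @param energy logical; include the five energy metabolites.
#' @return An object of class \code{panel_schema}: a list with
#'   \code{metabolite_names} (ordered character vector), \code{class_of}
#'   (named character vector mapping analyte to class) and
#'   \code{counts_by_class}.
#' @examples
#' sch <- panel_schema()
#' sch$counts_by_class
#' @export
panel_schema <- function(energy = TRUE) {
  core <- list(
    acylcarnitine  = .AC_NAMES,
    amino_acid     = .AA_NAMES,
    biogenic_amine = .BA_NAMES,
    hexoses        = "Hexoses",
    PC_aa          = .PC_AA_NAMES,
    PC_ae          = .PC_AE_NAMES,
    lysoPC         = .LPC_NAMES,
    SM             = .SM_NAMES
  )
  if (energy) core$energy <- .ENERGY_NAMES
  nm <- unlist(core, use.names = FALSE)
  cls <- rep(names(core), lengths(core))
  names(cls) <- nm
  stopifnot(!anyDuplicated(nm))
  structure(
    list(
      metabolite_names = nm,
      class_of = cls,
      counts_by_class = vapply(core, length, integer(1)),
      has_energy = energy
    ),
    class = "panel_schema"
  )
}

#' @export
print.panel_schema <- function(x, ...) {
  cat("<panel_schema> ", length(x$metabolite_names), " analytes\n", sep = "")
  print(x$counts_by_class)
  invisible(x)
}

#' Export a panel schema as JSON
#'
#' Writes the analyte roster with class assignments and the structured parse
#' of each name so that downstream consumers can audit membership decisions
#' (e.g. which amino acids count as essential).
#'
#' @param schema a \code{panel_schema}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_schema_json <- function(schema, path) {
  doc <- list(
    n_analytes = length(schema$metabolite_names),
    counts_by_class = as.list(schema$counts_by_class),
    analytes = lapply(schema$metabolite_names, function(nm) {
      p <- parse_metabolite_name(nm)
      c(list(name = nm, class = unname(schema$class_of[[nm]])),
        p[setdiff(names(p), "name")])
    }),
    essential_amino_acids = .ESSENTIAL_AA
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Nine-essential convention; documented in the schema JSON export.
.ESSENTIAL_AA <- c("His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val")

#' Parse a panel metabolite name
#'
#' Decomposes an analyte identifier into its structured fields. Lipid names
#' follow the panel nomenclature: \code{aa} marks two fatty-acid residues in
#' ester linkage (diacyl), \code{ae} an ester plus an ether linkage
#' (acyl-alkyl), and a single \code{a} one acyl residue; \code{Cx:y} gives
#' total carbons and double bonds; \code{-OH} marks hydroxylation and
#' \code{-DC} a dicarboxyl acylcarnitine.
#'
#' @param name a single analyte name, e.g. \code{"PC aa C36:6"},
#'   \code{"C14:1-OH"}, \code{"lysoPC a C26:1"} or \code{"Gln"}.
#' @return A list. For lipids and acylcarnitines: \code{kind = "lipid"},
#'   \code{family} (PC, lysoPC, SM or acylcarnitine), \code{bond} (aa, ae, a
#'   or none), \code{carbons}, \code{double_bonds}, \code{hydroxyl},
#'   \code{dicarboxyl}, \code{methyl}. For everything else: \code{kind} in
#'   amino_acid, biogenic_amine, hexoses, energy and the \code{name} token.
#' @examples
#' parse_metabolite_name("PC aa C36:6")
#' parse_metabolite_name("C14:1-OH")
#' @export
parse_metabolite_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lipid <- function(family, bond, carbons, double_bonds,
                    hydroxyl = FALSE, dicarboxyl = FALSE, methyl = FALSE) {
    list(kind = "lipid", name = name, family = family, bond = bond,
         carbons = as.integer(carbons), double_bonds = as.integer(double_bonds),
         hydroxyl = hydroxyl, dicarboxyl = dicarboxyl, methyl = methyl)
  }
  m <- regmatches(name, regexec("^PC (aa|ae) C([0-9]+):([0-9]+)$", name))[[1]]
  if (length(m)) return(lipid("PC", m[2], m[3], m[4]))
  m <- regmatches(name, regexec("^lysoPC (a|e) C([0-9]+):([0-9]+)$", name))[[1]]
  if (length(m)) return(lipid("lysoPC", m[2], m[3], m[4]))
  m <- regmatches(name, regexec("^SM (\\(OH\\) )?C([0-9]+):([0-9]+)$", name))[[1]]
  if (length(m)) {
    return(lipid("SM", "none", m[3], m[4], hydroxyl = nzchar(m[2])))
  }
  m <- regmatches(
    name,
    regexec("^C([0-9]+)(:([0-9]+))?(-M)?(-OH)?(-DC)?$", name)
  )[[1]]
  if (length(m)) {
    return(lipid("acylcarnitine", "none", m[2],
                 if (nzchar(m[4])) m[4] else 0L,
                 hydroxyl = nzchar(m[6]), dicarboxyl = nzchar(m[7]),
                 methyl = nzchar(m[5])))
  }
  token_class <- c(
    stats::setNames(rep("amino_acid", length(.AA_NAMES)), .AA_NAMES),
    stats::setNames(rep("biogenic_amine", length(.BA_NAMES)), .BA_NAMES),
    Hexoses = "hexoses",
    stats::setNames(rep("energy", length(.ENERGY_NAMES)), .ENERGY_NAMES)
  )
  if (name %in% names(token_class)) {
    return(list(kind = unname(token_class[[name]]), name = name))
  }
  stop("unrecognized metabolite nomenclature: '", name, "'", call. = FALSE)
}

#' Format a parsed metabolite name back to its canonical string
#'
#' Inverse of \code{\link{parse_metabolite_name}}; the round trip is the
#' identity on every name of the default schema.
#'
#' @param parsed a list as returned by \code{parse_metabolite_name}.
#' @return A single character string.
#' @export
format_metabolite_name <- function(parsed) {
  if (parsed$kind != "lipid") return(parsed$name)
  cxy <- paste0("C", parsed$carbons, ":", parsed$double_bonds)
  switch(parsed$family,
    PC = paste("PC", parsed$bond, cxy),
    lysoPC = paste("lysoPC", parsed$bond, cxy),
    SM = if (parsed$hydroxyl) paste("SM (OH)", cxy) else paste("SM", cxy),
    acylcarnitine = {
      s <- paste0("C", parsed$carbons)
      if (parsed$double_bonds > 0) s <- paste0(s, ":", parsed$double_bonds)
      if (parsed$methyl) s <- paste0(s, "-M")
      if (parsed$hydroxyl) s <- paste0(s, "-OH")
      if (parsed$dicarboxyl) s <- paste0(s, "-DC")
      s
    },
    stop("unknown lipid family: ", parsed$family)
  )
}
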