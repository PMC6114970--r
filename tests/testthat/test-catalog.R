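catalog <- build_default_catalog(panel_schema(energy = TRUE))

eval_one <- function(name, sample) {
  evaluate_expression(catalog$definitions[[name]], sample)
}

test_that("worked ratio examples evaluate to hand-computed values", {
  s <- c(Leu = 140, Ile = 60, Val = 220, Tyr = 60, Phe = 57,
         Gln = 800, Glu = 40)
  expect_equal(as.numeric(eval_one("BCAA", s)), 420)
  expect_equal(as.numeric(eval_one("Fischer", s)), 420 / 117,
               tolerance = 1e-12)
  expect_equal(as.numeric(eval_one("Gln/Glu", s)), 20)

  d9 <- c("PC ae C36:1" = 1, "PC ae C38:1" = 1, "PC ae C42:1" = 1,
          "PC ae C42:0" = 1)
  expect_equal(as.numeric(eval_one("Desaturase 9", d9)), 3)
})

test_that("zero denominators and missing leaves become reasoned missing", {
  v <- eval_one("Gln/Glu", c(Gln = 800, Glu = 0))
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "zero denominator")
  v2 <- eval_one("Gln/Glu", c(Gln = 800))
  expect_true(is.na(v2))
  expect_match(attr(v2, "reason"), "missing leaf: Glu")
})

test_that("catalog is complete, unique and large enough", {
  nms <- names(catalog$definitions)
  expect_false(anyDuplicated(nms) > 0)
  expect_gte(length(nms), 70)
  required <- c(
    "Essential AA", "Non-essential AA", "Gluc AA", "BCAA", "Arom AA",
    "Ala+Asp+Glu", "Total AA", "Total AC", "C2+C3", "C16+C18", "C16+C18:1",
    "C16-OH+C18:1-OH", "Total LPC", "Total PC aa", "Total PC ae", "Total SM",
    "Structural lipids", "Desaturase 9", "Desaturase 6", "Fischer",
    "Val/Phe", "Xle/Phe", "C5/C4", "Tyr/Ser", "Gly/Ala", "Gly/Gln",
    "Lac/Pyr", "CPT2 (C16+C18:1)/C2", "C14:1/C4", "C14:1-OH/C9", "C14/C9",
    "C14:1/C9", "C16/C3", "ELOVL2", "Met-SO", "Met-SO/Met", "ADMA", "SDMA",
    "Total DMA", "ADMA/Arg", "SDMA/Arg", "Total DMA/Arg", "Gln/Glu",
    "(Glu+Asp+Ala)/Gln", "(Gln/Glu)/Asp", "Glu/Hexoses", "Hexoses/Ser",
    "Hexoses/Gly", "Hexoses/Ala", "Glu/Orn", "Pro/Orn", "Orn/Arg",
    "Putrescine/Orn", "Spermidine/Putrescine", "Spermine/Spermidine",
    "ALT (Ala/Glu)", "AST (Asp/Glu)", "(Glu/Hexoses)/(Ala/Glu)",
    "((Glu/Gln)/Hexoses)/(Ala/Glu)", "Ser/C2", "Ser/Gln", "Ser/Thr",
    "GCKR (PC aa C42:0/PC ae C32:3)", "GCKR (PC aa C32:2/PC ae C34:2)",
    "(Ser/C2)/(Gln/Glu)", "(Ser/C2)/((Gln/Glu)/Asp)",
    "(PC aa C32:2/PC ae C34:2)/(Gln/Glu)",
    "(PC aa C32:2/PC ae C34:2)/((Gln/Glu)/Asp)",
    "Hexoses/Lac", "Fum/Hexoses", "Suc/Hexoses", "Hexoses/(Ala+Gly+Ser)",
    "Hexoses/(C14:1/C4)", "Hexoses/(C18:1/C8)", "Hexoses/(C16/C3)",
    "Hexoses/CPT2", "Hexoses/PHGDH", "Hexoses/AcylC-DC",
    "Hexoses/lysoPC a C26:1", "Hexoses/lysoPC a C28:1",
    "SFA", "MUFA", "(SFA/MUFA)/(Asp/Gln)", "Phe/((Gln/Glu)/Asp)",
    "Total DMA/((Gln/Glu)/Asp)", "Taurine/((Gln/Glu)/Asp)",
    "BC signature (Val/Phe)", "BC signature (Xle/Phe)",
    "Structural lipids/Gln", "Structural lipids/Hexoses"
  )
  expect_true(all(required %in% nms))
  # every entry resolves against the energy-extended schema
  expect_true(all(catalog$available))
})

test_that("energy-dependent entries are unavailable on the core schema", {
  expect_warning(core_cat <- build_default_catalog(panel_schema(FALSE)),
                 "Lac/Pyr")
  expect_false(core_cat$available[["Lac/Pyr"]])
  expect_true(core_cat$available[["Gln/Glu"]])
  # unavailable entries are retained, not dropped
  expect_true("Lac/Pyr" %in% names(core_cat$definitions))
})

test_that("breast-cancer signature matches hand arithmetic and scales with degree 1", {
  s <- c("PC aa C36:6" = 1, Val = 220, Phe = 57, Taurine = 60,
         "C10:2" = 0.05, "PC aa C28:1" = 2)
  out <- bc_signature(s)
  # (220/57)/60 = 0.0643; 1/0.0643 = 15.546; /0.05 = 310.9
  expect_equal(out$signature, 1 / ((220 / 57) / 60) / 0.05, tolerance = 1e-12)
  expect_equal(out$signature, 310.909, tolerance = 1e-4)
  expect_equal(out$pc_aa_c28_1, 2)

  ones <- c("PC aa C36:6" = 1, Val = 1, Phe = 1, Taurine = 1,
            "C10:2" = 1, "PC aa C28:1" = 1)
  expect_equal(bc_signature(ones)$signature, 1)

  expect_equal(bc_signature(s * 2)$signature, 2 * out$signature,
               tolerance = 1e-12)
  # Xle variant uses the combined Leu+Ile channel
  sx <- c(s, Leu = 140, Ile = 60)
  xle <- bc_signature(sx, variant = "xle_phe")$signature
  expect_equal(xle, 1 / (((140 + 60) / 57) / 60) / 0.05, tolerance = 1e-12)
})

test_that("pure ratios are scale-invariant and sums scale linearly", {
  sch <- panel_schema(energy = TRUE)
  set.seed(7)
  for (rep in 1:5) {
    s <- stats::setNames(stats::runif(length(sch$metabolite_names), 0.5, 50),
                         sch$metabolite_names)
    cmul <- stats::runif(1, 0.1, 10)
    for (nm in c("Gln/Glu", "Fischer", "Lac/Pyr", "Desaturase 9",
                 "(SFA/MUFA)/(Asp/Gln)", "(Ser/C2)/(Gln/Glu)")) {
      expect_equal(as.numeric(eval_one(nm, s * cmul)),
                   as.numeric(eval_one(nm, s)), tolerance = 1e-10)
    }
    for (nm in c("BCAA", "Total AA", "Structural lipids")) {
      expect_equal(as.numeric(eval_one(nm, s * cmul)),
                   cmul * as.numeric(eval_one(nm, s)), tolerance = 1e-10)
    }
    # degree -1 composite: (Ser/C2)/((Gln/Glu)/Asp) gains one power of c
    expect_equal(as.numeric(eval_one("(Ser/C2)/((Gln/Glu)/Asp)", s * cmul)),
                 cmul * as.numeric(eval_one("(Ser/C2)/((Gln/Glu)/Asp)", s)),
                 tolerance = 1e-10)
  }
})

test_that("catalog evaluation propagates missingness and never yields Inf", {
  tab <- make_full_table(fill = 2, n = 3)
  tab$conc[2, "Glu"] <- NA
  ft <- evaluate_catalog(tab, catalog)
  expect_equal(nrow(ft$features), 3)
  expect_true(is.na(ft$features[2, "Gln/Glu"]))
  expect_false(is.na(ft$features[1, "Gln/Glu"]))
  expect_false(is.na(ft$features[2, "BCAA"]))  # Glu-independent survives
  expect_false(any(is.infinite(ft$features)))
  # determinism / order stability
  ft2 <- evaluate_catalog(tab, catalog)
  expect_identical(ft$features, ft2$features)
})

test_that("catalog JSON export serializes expressions and degrees", {
  path <- tempfile(fileext = ".json")
  export_catalog_json(catalog, path)
  doc <- jsonlite::read_json(path)
  expect_length(doc, length(catalog$definitions))
  byname <- stats::setNames(doc, vapply(doc, `[[`, "", "name"))
  expect_equal(byname[["Gln/Glu"]]$degree, 0)
  expect_equal(byname[["BCAA"]]$degree, 1)
  expect_equal(byname[["BC signature (Val/Phe)"]]$degree, 1)
  expect_match(byname[["Fischer"]]$expression, "Leu")
})
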