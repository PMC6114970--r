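test_that("default schema has the canonical class composition", {
  sch <- panel_schema(energy = FALSE)
  expect_length(sch$metabolite_names, 186)
  expect_false(anyDuplicated(sch$metabolite_names) > 0)
  expect_identical(
    unname(sch$counts_by_class[c("acylcarnitine", "amino_acid",
                                 "biogenic_amine", "hexoses", "PC_aa",
                                 "PC_ae", "lysoPC", "SM")]),
    c(40L, 21L, 19L, 1L, 38L, 38L, 14L, 15L)
  )
  sche <- panel_schema(energy = TRUE)
  expect_length(sche$metabolite_names, 191)
  expect_true(all(c("Lac", "Pyr", "Fum", "Suc") %in% sche$metabolite_names))
})

test_that("nomenclature parser decodes lipid names", {
  p <- parse_metabolite_name("PC aa C36:6")
  expect_equal(p[c("family", "bond", "carbons", "double_bonds")],
               list(family = "PC", bond = "aa", carbons = 36L,
                    double_bonds = 6L))
  p <- parse_metabolite_name("C14:1-OH")
  expect_equal(p$family, "acylcarnitine")
  expect_equal(p$carbons, 14L)
  expect_equal(p$double_bonds, 1L)
  expect_true(p$hydroxyl)
  expect_false(p$dicarboxyl)
  p <- parse_metabolite_name("lysoPC a C26:1")
  expect_equal(p[c("family", "bond", "carbons", "double_bonds")],
               list(family = "lysoPC", bond = "a", carbons = 26L,
                    double_bonds = 1L))
  expect_true(parse_metabolite_name("SM (OH) C14:1")$hydroxyl)
  expect_true(parse_metabolite_name("C5-M-DC")$dicarboxyl)
  expect_equal(parse_metabolite_name("Gln")$kind, "amino_acid")
  expect_equal(parse_metabolite_name("Taurine")$kind, "biogenic_amine")
  expect_error(parse_metabolite_name("PC xx C10:1"), "unrecognized")
  expect_error(parse_metabolite_name("frobnicate"), "frobnicate")
})

test_that("parse/format round trip is the identity on every schema name", {
  sch <- panel_schema(energy = TRUE)
  rt <- vapply(sch$metabolite_names,
               function(n) format_metabolite_name(parse_metabolite_name(n)),
               character(1))
  expect_identical(unname(rt), sch$metabolite_names)
})

test_that("header dialects normalize to canonical names", {
  sch <- panel_schema()
  expect_identical(
    normalize_analyte_names(c("PC.aa.C36.6", "PC_ae_C38_3", "lysoPC.a.C26.1",
                              "C14.1.OH", "Tau", "H1", "Lactate", "nope"),
                            sch),
    c("PC aa C36:6", "PC ae C38:3", "lysoPC a C26:1", "C14:1-OH",
      "Taurine", "Hexoses", "Lac", NA)
  )
})

test_that("write-then-read round trip preserves values and missing mask", {
  tab <- make_full_table(fill = 1.25, n = 4)
  tab$conc[2, "Gln"] <- NA
  tab$conc[, "Glu"] <- c(40.5, 39.25, 41, 38.125)
  path <- tempfile(fileext = ".csv")
  write_panel_table(tab, path)
  tab2 <- load_panel_table(path, panel_schema(energy = TRUE),
                           lod_policy = "keep")
  expect_identical(tab2$sample_id, tab$sample_id)
  expect_identical(tab2$group, tab$group)
  expect_identical(tab2$conc, tab$conc)
  expect_true(is.na(tab2$conc[2, "Gln"]))
})

test_that("loader maps dotted headers, rejects duplicates and bad files", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,PC.aa.C36.6,Gln",
               "a,control,1.5,800", "b,case,3.0,100"), path)
  tab <- load_panel_table(path)
  expect_identical(colnames(tab$conc), c("PC aa C36:6", "Gln"))
  expect_equal(unname(tab$conc[, "PC aa C36:6"]), c(1.5, 3.0))

  writeLines(c("sample_id,group,Gln", "a,control,1", "a,case,2"), path)
  expect_error(load_panel_table(path), "duplicate")

  writeLines(c("sample_id,group,foo,bar", "a,control,1,2"), path)
  expect_error(suppressWarnings(load_panel_table(path)),
               "no recognizable analyte columns")
  expect_error(load_panel_table(tempfile()), "cannot read")
})

test_that("below-LOD zeros follow the configured policy", {
  conc <- matrix(c(0, 2, 4, 0, 1, 3), 3, 2,
                 dimnames = list(NULL, c("Gln", "Glu")))
  half <- apply_lod_policy(conc, "half_min")
  expect_equal(unname(half[1, "Gln"]), 1)   # half of min positive 2
  expect_equal(unname(half[1, "Glu"]), 0.5) # half of min positive 1
  expect_true(is.na(apply_lod_policy(conc, "missing")[1, "Gln"]))
  expect_identical(apply_lod_policy(conc, "keep"), conc)
})

test_that("validation reports errors and warnings without raising", {
  tab <- make_full_table(fill = 2)
  rep1 <- validate_panel(tab, panel_schema(energy = TRUE))
  expect_true(rep1$passed)
  expect_equal(nrow(rep1$errors), 0)

  # negative value: bypass the constructor check to exercise validation
  tab$conc[1, "Gln"] <- -1
  rep2 <- validate_panel(tab, panel_schema(energy = TRUE))
  expect_false(rep2$passed)
  expect_equal(nrow(rep2$errors), 1)
  expect_match(rep2$errors$message, "negative")

  # unknown column is a warning only
  tab3 <- make_full_table(fill = 2)
  tab3$conc <- cbind(tab3$conc, foo = 1)
  rep3 <- validate_panel(tab3, panel_schema(energy = TRUE))
  expect_true(rep3$passed)
  expect_true("foo" %in% rep3$warnings$analyte)

  # idempotence
  expect_identical(validate_panel(tab3, panel_schema(energy = TRUE)), rep3)
})

test_that("reference flags follow the printed cut-offs", {
  rng <- reference_ranges()
  expect_equal(rng$lac_pyr_upper_normal, 25.8)
  expect_equal(rng$phe_normal_range, c(40, 74))

  tab <- make_full_table(fill = 1, n = 4)
  tab$conc[, "Lac"] <- c(100, 50, 100, 100)
  tab$conc[, "Pyr"] <- c(3, 3, 0, 4)
  tab$conc[, "Phe"] <- c(89.3, 57, 57, 57)
  tab$conc[, "Gln"] <- c(100, 800, 800, 800)
  fl <- reference_flags(tab)
  # Lac=100, Pyr=3 -> 33.33 > 25.8
  expect_true(fl$oxphos_deficiency[1])
  expect_false(fl$oxphos_deficiency[2])   # 50/3 = 16.7
  expect_true(is.na(fl$oxphos_deficiency[3]))  # zero denominator
  expect_true(fl$hyperphenylalaninemia[1])     # 89.3 > 74
  expect_false(fl$hyperphenylalaninemia[2])
  expect_true(fl$hypoglutaminemia[1])
  expect_false(fl$hypoglutaminemia[2])

  # all analytes at normal midpoints -> no flags
  tab2 <- make_full_table(fill = 1, n = 1)
  tab2$conc[, "Lac"] <- 20; tab2$conc[, "Pyr"] <- 1
  tab2$conc[, "Phe"] <- 57; tab2$conc[, "Gln"] <- 800
  tab2$conc[, "Glu"] <- 20; tab2$conc[, "Asp"] <- 2.5
  fl2 <- reference_flags(tab2)
  expect_false(any(unlist(fl2[, -1])))

  # unit consistency: common rescaling of Lac and Pyr leaves the flag alone
  tab3 <- tab
  tab3$conc[, "Lac"] <- tab$conc[, "Lac"] * 7.3
  tab3$conc[, "Pyr"] <- tab$conc[, "Pyr"] * 7.3
  expect_identical(reference_flags(tab3)$oxphos_deficiency,
                   fl$oxphos_deficiency)
})

test_that("flags for absent analytes are skipped with a warning", {
  conc <- matrix(800, 2, 1, dimnames = list(NULL, "Gln"))
  tab <- sample_table(conc)
  expect_warning(expect_warning(fl <- reference_flags(tab), "Lac"), "Phe")
  expect_false(is.null(fl$hypoglutaminemia))
  expect_null(fl$oxphos_deficiency)
})

test_that("schema JSON export lists every analyte with its parse", {
  path <- tempfile(fileext = ".json")
  export_schema_json(panel_schema(energy = FALSE), path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$n_analytes, 186)
  expect_length(doc$analytes, 186)
  expect_equal(doc$analytes[[1]]$name, "C0")
  expect_length(doc$essential_amino_acids, 9)
})
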