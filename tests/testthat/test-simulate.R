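config <- default_cohort_config()

test_that("default config encodes the published reference levels", {
  expect_equal(unname(config$control_mean["Gln"]), 800)
  expect_equal(unname(config$control_mean["Glu"]), 40)
  expect_equal(unname(config$case_multiplier["Gln"]), 1 / 8)
  expect_equal(unname(config$case_multiplier["Glu"]), 10)
  expect_equal(unname(config$case_multiplier["Asp"]), 10)
  prov <- config$provenance
  expect_equal(prov$mean_source[prov$analyte == "Gln"], "printed")
  expect_equal(prov$mean_source[prov$analyte == "Ala"], "invented")
  expect_equal(prov$multiplier_source[prov$analyte == "Taurine"],
               "invented_direction_only")
  # directions reported in the study: up-markers multiplied above 1, the
  # decenoyl-carnitine channel reduced
  up <- c("Taurine", "Met-SO", "SM C18:0", "PC ae C38:3", "lysoPC a C26:1",
          "C14:1-OH", "PC aa C36:6")
  expect_true(all(config$case_multiplier[up] > 1))
  expect_lt(config$case_multiplier[["C10:2"]], 1)
})

test_that("case lactate mean is calibrated to the 76% exceedance target", {
  s <- sqrt(2 * log(1 + 0.25^2))
  ratio_means <- config$control_mean[["Lac"]] *
    config$case_multiplier[["Lac"]] / config$control_mean[["Pyr"]]
  implied <- 1 - pnorm((log(25.8) - log(ratio_means)) / s)
  expect_equal(implied, 0.76, tolerance = 1e-10)
})

test_that("cohorts are reproducible, positive and hit configured moments", {
  t1 <- simulate_cohort(config, "control", 50, seed = 11)
  t2 <- simulate_cohort(config, "control", 50, seed = 11)
  expect_identical(t1$conc, t2$conc)
  t3 <- simulate_cohort(config, "control", 50, seed = 12)
  expect_false(identical(t1$conc, t3$conc))
  expect_true(all(t1$conc > 0, na.rm = TRUE))
  expect_true(all(t1$group == "control"))

  ctrl <- simulate_cohort(config, "control", 1000, seed = 1)
  expect_lt(abs(mean(ctrl$conc[, "Gln"], na.rm = TRUE) - 800) / 800, 0.05)
  case <- simulate_cohort(config, "case", 1000, seed = 2)
  expect_lt(abs(mean(case$conc[, "Gln"], na.rm = TRUE) - 100) / 100, 0.10)
})

test_that("sample moments converge to the configured moments at n = 1e4", {
  noLOD <- default_cohort_config(lod_rate = 0)
  big <- simulate_cohort(noLOD, "control", 10000, seed = 21)
  for (a in c("Gln", "Glu", "Hexoses", "C2")) {
    mu <- noLOD$control_mean[[a]]
    se <- mu * 0.25 / sqrt(10000)
    expect_lt(abs(mean(big$conc[, a]) - mu), 3 * se)
    # CV of the draws matches the configured 0.25 within a few percent
    expect_lt(abs(sd(big$conc[, a]) / mean(big$conc[, a]) - 0.25), 0.02)
  }
})

test_that("below-LOD injection respects the configured policy and rate", {
  masked <- default_cohort_config(lod_rate = 0.1, lod_policy = "missing")
  tab <- simulate_cohort(masked, "control", 200, seed = 5)
  frac <- mean(is.na(tab$conc))
  expect_lt(abs(frac - 0.1), 0.01)
  kept <- default_cohort_config(lod_rate = 0)
  tab2 <- simulate_cohort(kept, "control", 200, seed = 5)
  expect_false(anyNA(tab2$conc))
})

test_that("continuum endpoints match control and case and Gln/Glu is monotone", {
  cont <- simulate_continuum(config, n_per_grade = 300, seed = 8)
  grades <- names(config$continuum_grades)
  expect_setequal(unique(cont$group), grades)
  g0 <- cont$conc[cont$group == "met_syn_0", ]
  g1 <- cont$conc[cont$group == "invasive", ]
  # endpoint means coincide with the control / case configurations
  expect_lt(abs(mean(g0[, "Gln"], na.rm = TRUE) - 800) / 800, 0.05)
  expect_lt(abs(mean(g1[, "Gln"], na.rm = TRUE) - 100) / 100, 0.10)
  gg <- vapply(grades, function(g) {
    sub <- cont$conc[cont$group == g, ]
    mean(sub[, "Gln"] / sub[, "Glu"], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(gg) < 0))  # strictly decreasing along the continuum
  expect_error(
    simulate_continuum(config, 5, seed = 1, grades = c(a = -0.2, b = 1)),
    "\\[0, 1\\]")
  expect_error(simulate_continuum(config, 5, seed = 1, grades = numeric()),
               "nonempty")
})

test_that("generator + catalog + discriminant reproduce the case phenotype", {
  ctrl <- simulate_cohort(config, "control", 40, seed = 31)
  case <- simulate_cohort(config, "case", 40, seed = 32)
  tab <- sample_table(rbind(ctrl$conc, case$conc),
                      group = c(ctrl$group, case$group),
                      sample_id = c(ctrl$sample_id, case$sample_id))
  feats <- evaluate_catalog(tab, build_default_catalog(panel_schema(TRUE)))
  is_case <- feats$group == "case"
  f <- feats$features
  expect_lt(mean(f[is_case, "Gln/Glu"], na.rm = TRUE),
            mean(f[!is_case, "Gln/Glu"], na.rm = TRUE))
  expect_gt(mean(f[is_case, "BC signature (Val/Phe)"], na.rm = TRUE),
            mean(f[!is_case, "BC signature (Val/Phe)"], na.rm = TRUE))
  # the SFA/MUFA-to-glutaminolysis discriminant separates the groups
  disc <- f[, "(SFA/MUFA)/(Asp/Gln)"]
  ok <- !is.na(disc)
  expect_gt(roc_auc(-disc[ok], is_case[ok])$auc, 0.95)
})
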