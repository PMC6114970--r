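# End-to-end driver: simulate or load -> validate -> ratio features ->
# log-transform -> univariate screen -> MCCV -> operating point ->
# permutation test -> serialized report.

#' Default pipeline configuration
#'
#' @param n_controls,n_cases cohort sizes when simulating (defaults mirror
#'   an exploratory-scale design of 31 controls vs 59 cases).
#' @param input_table optional path to a delimited concentration table; when
#'   given, simulation is skipped.
#' @param features feature set for the discriminant; the default is the
#'   two-feature breast-cancer signature (equation + PC aa C28:1).
#' @param variant signature variant, \code{"val_phe"} or \code{"xle_phe"}.
#' @param n_iterations MCCV iterations.
#' @param n_perm label permutations for the accuracy test.
#' @param seed master seed for all randomness.
#' @return A named list understood by \code{\link{run_pipeline}}.
#' @export
pipeline_config <- function(n_controls = 31L, n_cases = 59L,
                            input_table = NULL,
                            features = c("bc_signature", "PC aa C28:1"),
                            variant = "val_phe", n_iterations = 100L,
                            n_perm = 100L, seed = 1L) {
  list(n_controls = n_controls, n_cases = n_cases, input_table = input_table,
       features = features, variant = variant, n_iterations = n_iterations,
       n_perm = n_perm, seed = seed)
}

#' Run the full discriminant pipeline
#'
#' Executes load/simulate, validation, signature computation,
#' log-transformation, univariate screening, Monte-Carlo cross-validation,
#' Youden operating point on the pooled held-out predictions, the
#' label-permutation test and (when Lac/Pyr is available) the univariate
#' logistic risk model. All randomness derives from the configured seed, so
#' identical configurations produce identical reports.
#'
#' @param config a list from \code{\link{pipeline_config}} or a path to a
#'   YAML file with the same fields.
#' @return Object of class \code{report_bundle}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  known <- c("bc_signature", panel_schema(energy = TRUE)$metabolite_names)
  bad <- setdiff(config$features, known)
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cc <- default_cohort_config()
  if (!is.null(config$input_table)) {
    tab <- load_panel_table(config$input_table)
  } else {
    ctrl <- simulate_cohort(cc, "control", config$n_controls,
                            seed = config$seed)
    case <- simulate_cohort(cc, "case", config$n_cases,
                            seed = config$seed + 1L)
    tab <- sample_table(rbind(ctrl$conc, case$conc),
                        group = c(ctrl$group, case$group),
                        sample_id = c(ctrl$sample_id, case$sample_id))
  }
  validation <- validate_panel(tab)
  if (!validation$passed) {
    stop("input table failed validation: ", nrow(validation$errors),
         " errors", call. = FALSE)
  }
  sig <- bc_signature(tab, variant = config$variant)
  cols <- list()
  for (f in config$features) {
    cols[[f]] <- if (f == "bc_signature") sig$signature else tab$conc[, f]
  }
  feats <- feature_table(do.call(cbind, cols), group = tab$group,
                         sample_id = tab$sample_id)
  colnames(feats$features) <- names(cols)
  lf <- log_transform(feats)
  screen <- univariate_screen(lf)
  cfg <- mccv_config(n_iterations = config$n_iterations,
                     seed = config$seed)
  y <- as.integer(tab$group == "case")  # cases are the positive class
  mccv <- mccv_evaluate(lf, labels = y, config = cfg)
  roc <- roc_auc(mccv$pooled$score, mccv$pooled$truth)
  op <- operating_point(roc, mccv$pooled$score, mccv$pooled$truth)
  ci <- bootstrap_auc_ci(mccv$pooled$score, mccv$pooled$truth,
                         n_boot = 200, seed = config$seed)
  perm <- permutation_test(lf, labels = y, config = cfg,
                           n_perm = config$n_perm)
  logistic <- NULL
  if (all(c("Lac", "Pyr") %in% colnames(tab$conc))) {
    lp <- tab$conc[, "Lac"] / tab$conc[, "Pyr"]
    logistic <- fit_univariate_logistic(lp, tab$group == "case")
  }
  structure(
    list(
      input_summary = list(n_samples = nrow(tab$conc),
                           groups = as.list(table(tab$group)),
                           features = config$features,
                           variant = config$variant, seed = config$seed),
      validation = list(passed = validation$passed,
                        n_missing = validation$n_missing),
      screen = screen,
      mccv = list(mean_auc = mccv$mean_auc,
                  mean_accuracy = mccv$mean_accuracy,
                  pooled_auc = roc$auc, auc_ci95 = as.numeric(ci),
                  sensitivity = op$sensitivity, specificity = op$specificity,
                  ppv = op$ppv, npv = op$npv,
                  permutation_p = perm$p_value),
      logistic = if (!is.null(logistic)) {
        list(intercept = logistic$intercept, slope = logistic$slope,
             odds_ratio = logistic$odds_ratio,
             penalized = logistic$penalized)
      }
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat(sprintf("  samples: %d (%s)\n", x$input_summary$n_samples,
              paste(names(x$input_summary$groups),
                    unlist(x$input_summary$groups),
                    sep = ":", collapse = ", ")))
  cat(sprintf("  pooled held-out AUC %.4f [%.4f, %.4f]\n",
              x$mccv$pooled_auc, x$mccv$auc_ci95[1], x$mccv$auc_ci95[2]))
  cat(sprintf("  mean MCCV AUC %.4f | accuracy %.4f | permutation p %.4g\n",
              x$mccv$mean_auc, x$mccv$mean_accuracy, x$mccv$permutation_p))
  cat(sprintf("  Youden point: sens %.2f%% spec %.2f%% PPV %.2f%% NPV %.2f%%\n",
              100 * x$mccv$sensitivity, 100 * x$mccv$specificity,
              100 * x$mccv$ppv, 100 * x$mccv$npv))
  invisible(x)
}

#' Serialize a report bundle
#'
#' Writes the metrics as JSON and the univariate screen as TSV next to it.
#'
#' @param bundle a \code{report_bundle}.
#' @param path JSON output path; the screen table goes to
#'   \code{sub(".json", "_screen.tsv", path)}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(bundle, path) {
  out <- unclass(bundle)
  screen <- out$screen
  out$screen <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  utils::write.table(screen, sub("\\.json$", "_screen.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
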