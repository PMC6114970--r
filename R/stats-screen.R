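# Log-transform, univariate screening with BH FDR, Pearson correlations.

#' Natural-log transform of a feature table
#'
#' Applied element-wise to normalize right-skewed concentration
#' distributions before statistics; missing values are preserved. Zeros are
#' expected to have been handled by the below-LOD policy upstream, so any
#' nonpositive finite value is an error.
#'
#' @param features a \code{feature_table} (or numeric matrix).
#' @return The same container with log-transformed values.
#' @export
log_transform <- function(features) {
  m <- if (inherits(features, "feature_table")) features$features else features
  if (any(m <= 0, na.rm = TRUE)) {
    stop("nonpositive values present; apply a below-LOD policy before ",
         "log-transforming", call. = FALSE)
  }
  m <- log(m)
  if (inherits(features, "feature_table")) {
    features$features <- m
    features
  } else m
}

#' Univariate group screening with FDR control
#'
#' Per feature: Welch's t-test for two groups, one-way ANOVA for more;
#' Benjamini-Hochberg adjustment across all tested features. Features with
#' fewer than 2 non-missing values in some group are skipped with a note;
#' degenerate features (zero variance in every group) get p = 1 with a
#' warning.
#'
#' @param features a \code{feature_table}.
#' @param labels group label per sample; defaults to the table's groups.
#' @param min_per_group minimum non-missing observations per group.
#' @return Data frame with feature, statistic, p, fdr and a note column,
#'   ordered as the input features.
#' @export
univariate_screen <- function(features, labels = features$group,
                              min_per_group = 2L) {
  m <- features$features
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups", call. = FALSE)
  res <- lapply(colnames(m), function(f) {
    x <- m[, f]
    ok <- !is.na(x)
    tab <- table(labels[ok])
    if (any(tab < min_per_group) || sum(tab > 0) < 2) {
      return(data.frame(feature = f, statistic = NA_real_, p = NA_real_,
                        note = "insufficient data", stringsAsFactors = FALSE))
    }
    vars <- tapply(x[ok], droplevels(labels[ok]), stats::var)
    if (all(vars == 0, na.rm = TRUE)) {
      warning("feature '", f, "' has zero variance in every group",
              call. = FALSE)
      return(data.frame(feature = f, statistic = NA_real_, p = 1,
                        note = "degenerate", stringsAsFactors = FALSE))
    }
    if (nlevels(droplevels(labels[ok])) == 2) {
      tt <- stats::t.test(x[ok] ~ droplevels(labels[ok]))
      data.frame(feature = f, statistic = unname(tt$statistic),
                 p = tt$p.value, note = "welch_t", stringsAsFactors = FALSE)
    } else {
      fit <- stats::aov(x[ok] ~ droplevels(labels[ok]))
      s <- summary(fit)[[1]]
      data.frame(feature = f, statistic = s[["F value"]][1],
                 p = s[["Pr(>F)"]][1], note = "anova",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  tested <- !is.na(out$p) & out$note != "degenerate"
  out$fdr <- NA_real_
  out$fdr[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$fdr[out$note == "degenerate"] <- 1
  out
}

#' Per-feature Pearson correlations against a numeric target
#'
#' Product-moment r with a two-sided test and BH FDR across features.
#' Features with fewer than 3 complete pairs, or constant over the complete
#' pairs, are reported as missing with a reason.
#'
#' @param features a \code{feature_table}.
#' @param target numeric vector, one value per sample.
#' @return Data frame with feature, n, r, p, fdr, note.
#' @export
pearson_correlations <- function(features, target) {
  m <- features$features
  stopifnot(length(target) == nrow(m))
  res <- lapply(colnames(m), function(f) {
    x <- m[, f]
    ok <- !is.na(x) & !is.na(target)
    if (sum(ok) < 3) {
      return(data.frame(feature = f, n = sum(ok), r = NA_real_, p = NA_real_,
                        note = "fewer than 3 pairs", stringsAsFactors = FALSE))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(target[ok]) == 0) {
      return(data.frame(feature = f, n = sum(ok), r = NA_real_, p = NA_real_,
                        note = "constant input", stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], target[ok], method = "pearson")
    data.frame(feature = f, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  tested <- !is.na(out$p)
  out$fdr[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out
}
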