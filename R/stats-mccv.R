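# Monte-Carlo cross-validation with balanced (class-stratified) 2/3
# subsampling, plus the label-permutation test built on top of it.

#' MCCV configuration
#'
#' @param n_iterations number of random train/test splits (default 100, the
#'   upper end of the 10-100 repeats used for performance estimation).
#' @param train_fraction fraction of each class used for training (2/3).
#' @param classifier \code{"logistic_l2"} (ridge-penalized logistic, the
#'   default) or \code{"plsda"} (2-component PLS-DA, requires mixOmics).
#' @param lambda ridge penalty for the logistic classifier.
#' @param seed integer seed; all randomness is local to the evaluation.
#' @return A list of class \code{mccv_config}.
#' @export
mccv_config <- function(n_iterations = 100L, train_fraction = 2 / 3,
                        classifier = c("logistic_l2", "plsda"),
                        lambda = 0.01, seed = 1L) {
  stopifnot(n_iterations >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 classifier = match.arg(classifier),
                 lambda = lambda, seed = as.integer(seed)),
            class = "mccv_config")
}

# Fit the configured classifier on standardized training data and return a
# function scoring new (unstandardized) rows. Standardization parameters are
# estimated on the training fold only.
.fit_classifier <- function(X, y, config) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  informative <- !is.na(sd) & sd > 0
  if (!any(informative)) {
    # no usable predictor: score every sample at the training prevalence
    prev <- mean(y)
    return(function(Xnew) rep(prev, nrow(Xnew)))
  }
  sd[!informative] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  if (config$classifier == "plsda") {
    if (!requireNamespace("mixOmics", quietly = TRUE)) {
      stop("classifier 'plsda' requires the mixOmics package", call. = FALSE)
    }
    fit <- mixOmics::plsda(Xs, factor(y, levels = c(0, 1)),
                           ncomp = min(2L, ncol(Xs)))
    return(function(Xnew) {
      Xn <- sweep(sweep(Xnew, 2, mu), 2, sd, "/")
      pr <- predict(fit, Xn)$predict
      pr[, "1", dim(pr)[3]]
    })
  }
  if (ncol(Xs) >= 2) {
    # glmnet warns about small classes on every fold; expected here
    fit <- suppressWarnings(
      glmnet::glmnet(Xs, factor(y, levels = c(0, 1)),
                     family = "binomial", alpha = 0,
                     lambda = config$lambda, standardize = FALSE))
    function(Xnew) {
      Xn <- sweep(sweep(Xnew, 2, mu), 2, sd, "/")
      as.numeric(predict(fit, Xn, type = "response"))
    }
  } else {
    df <- data.frame(y = y, x = Xs[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, df, family = stats::binomial()))
    function(Xnew) {
      Xn <- sweep(sweep(Xnew, 2, mu), 2, sd, "/")
      as.numeric(stats::predict(fit, data.frame(x = Xn[, 1]),
                                type = "response"))
    }
  }
}

#' Monte-Carlo cross-validated classification performance
#'
#' Per iteration: a class-stratified ("balanced") random subsample of 2/3 of
#' each class trains the classifier (including its standardization); the
#' held-out third is scored; held-out AUC and accuracy (probability
#' threshold 0.5) are recorded. Results are fully reproducible from the
#' configured seed and the caller's RNG state is untouched.
#'
#' @param features a \code{feature_table} or numeric matrix.
#' @param labels binary group labels; defaults to the table's groups.
#' @param config an \code{mccv_config}.
#' @return Object of class \code{mccv_result}: per-iteration \code{auc} and
#'   \code{accuracy}, their means, and the pooled held-out predictions
#'   (score, truth, iteration).
#' @export
mccv_evaluate <- function(features, labels = NULL, config = mccv_config()) {
  X <- if (inherits(features, "feature_table")) features$features else
    as.matrix(features)
  if (is.null(labels)) {
    if (!inherits(features, "feature_table")) {
      stop("labels are required", call. = FALSE)
    }
    labels <- features$group
  }
  y <- as_binary_labels(labels)
  cc <- stats::complete.cases(X) & !is.na(y)
  if (!all(cc)) {
    warning(sum(!cc), " samples with missing values excluded", call. = FALSE)
    X <- X[cc, , drop = FALSE]; y <- y[cc]
  }
  i0 <- which(y == 0); i1 <- which(y == 1)
  n_tr0 <- floor(config$train_fraction * length(i0))
  n_tr1 <- floor(config$train_fraction * length(i1))
  if (min(length(i0), length(i1)) < 3 || n_tr0 < 1 || n_tr1 < 1 ||
      n_tr0 >= length(i0) || n_tr1 >= length(i1)) {
    stop("a class is too small for a stratified 2/3 split", call. = FALSE)
  }
  res <- with_local_seed(config$seed, {
    auc <- acc <- numeric(config$n_iterations)
    pooled <- vector("list", config$n_iterations)
    for (it in seq_len(config$n_iterations)) {
      tr <- c(sample(i0, n_tr0), sample(i1, n_tr1))
      te <- setdiff(seq_along(y), tr)
      score <- .fit_classifier(X[tr, , drop = FALSE], y[tr], config)
      p <- score(X[te, , drop = FALSE])
      auc[it] <- roc_auc(p, y[te])$auc
      acc[it] <- mean((p > 0.5) == (y[te] == 1))
      pooled[[it]] <- data.frame(score = p, truth = y[te], iteration = it)
    }
    list(auc = auc, acc = acc, pooled = do.call(rbind, pooled))
  })
  structure(
    list(per_iteration = data.frame(iteration = seq_len(config$n_iterations),
                                    auc = res$auc, accuracy = res$acc),
         mean_auc = mean(res$auc), mean_accuracy = mean(res$acc),
         pooled = res$pooled, config = config),
    class = "mccv_result"
  )
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("<mccv_result> %d iterations | mean AUC %.4f | mean accuracy %.4f\n",
              nrow(x$per_iteration), x$mean_auc, x$mean_accuracy))
  invisible(x)
}

#' Label-permutation test of MCCV accuracy
#'
#' The observed statistic is the mean MCCV accuracy; the null distribution
#' is built by re-running the full MCCV evaluation under random label
#' permutations. The p-value uses the add-one convention
#' p = (#\{null >= observed\} + 1) / (n_perm + 1), so the smallest
#' attainable value is 1/(n_perm + 1).
#'
#' @param features a \code{feature_table} or matrix.
#' @param labels binary labels.
#' @param config an \code{mccv_config}; its \code{n_iterations} also governs
#'   each null re-evaluation.
#' @param n_perm number of permutations (1000 in the study protocol; smaller
#'   values keep exploratory runs fast).
#' @return List of class \code{permutation_result}: \code{observed_stat},
#'   \code{null_stats}, \code{p_value}.
#' @export
permutation_test <- function(features, labels = NULL,
                             config = mccv_config(), n_perm = 1000L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(labels) && inherits(features, "feature_table")) {
    labels <- features$group
  }
  y <- as_binary_labels(labels)
  observed <- mccv_evaluate(features, y, config)$mean_accuracy
  perms <- with_local_seed(config$seed + 10^6, {
    lapply(seq_len(n_perm), function(b) sample(y))
  })
  null_stats <- vapply(seq_len(n_perm), function(b) {
    cfg <- config
    cfg$seed <- config$seed + b
    mccv_evaluate(features, perms[[b]], cfg)$mean_accuracy
  }, numeric(1))
  p <- (sum(null_stats >= observed) + 1) / (n_perm + 1)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f | p = %.4g (%d permutations)\n",
              x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}
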