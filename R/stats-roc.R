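# ROC/AUC machinery: midrank AUC, threshold-sweep curve, Youden operating
# point, stratified bootstrap confidence interval.

#' ROC curve and AUC
#'
#' AUC is computed from the midrank (Mann-Whitney) statistic so that tied
#' scores contribute half wins; the curve is built by sweeping every distinct
#' score as a threshold (predict positive when score >= threshold). The curve
#' starts at (0,0), ends at (1,1) and its trapezoidal area equals the
#' midrank AUC.
#'
#' @param scores numeric vector; larger values indicate the positive class.
#' @param labels binary vector (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @return An object of class \code{roc_result}: list with \code{auc},
#'   \code{curve} (data frame fpr/tpr/threshold) and the inputs' class
#'   counts.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, 0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                      threshold = c(Inf, thr, -Inf))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d pos / %d neg)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have 2 levels", call. = FALSE)
    return(as.integer(labels == levels(labels)[2]))
  }
  u <- sort(unique(labels[!is.na(labels)]))
  if (length(u) != 2) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  as.integer(labels == u[2])
}

#' Operating-point metrics at the Youden-optimal threshold
#'
#' Chooses the threshold maximizing Youden's J = sensitivity + specificity
#' - 1 over the ROC curve (ties broken toward higher specificity, i.e. the
#' higher threshold) and reports the confusion-matrix metrics there.
#'
#' @param roc a \code{roc_result} from \code{\link{roc_auc}}.
#' @param scores,labels the vectors the ROC was computed from.
#' @return List with \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv} and the confusion counts.
#' @export
operating_point <- function(roc, scores, labels) {
  y <- as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  cv <- roc$curve[is.finite(roc$curve$threshold), ]
  j <- (cv$tpr - cv$fpr)
  best <- which(j == max(j))
  # ties toward higher specificity = lower fpr = higher threshold
  thr <- max(cv$threshold[best])
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  list(
    threshold = thr,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn)
  )
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls independently with replacement and returns
#' the percentile interval of the bootstrap AUC distribution. Degenerate
#' resamples cannot occur because resampling is stratified.
#'
#' @param scores,labels as in \code{\link{roc_auc}}.
#' @param n_boot number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed; randomness is local to the call.
#' @return Numeric vector \code{c(lo, hi)} with attribute \code{"aucs"}.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000, level = 0.95,
                             seed = 1L) {
  y <- as_binary_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  ipos <- which(y == 1); ineg <- which(y == 0)
  if (!length(ipos) || !length(ineg)) {
    stop("both classes must be present", call. = FALSE)
  }
  aucs <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ipos, length(ipos), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      roc_auc(scores[idx], y[idx])$auc
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
  structure(ci, aucs = aucs)
}

# Run code under a temporary RNG state; the caller's global state is
# restored afterwards so that stochastic operations never leak.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
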