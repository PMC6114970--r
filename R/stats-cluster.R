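# Unsupervised structure: agglomerative clustering of samples on
# autoscaled features.

#' Hierarchical clustering of samples
#'
#' Agglomerates samples by Ward linkage (\code{ward.D2}) on the Euclidean
#' distance between autoscaled (z-scored per feature) values, the common
#' choice for metabolomics heatmaps. Features that are constant are dropped;
#' distances use pairwise-complete values when missing data are present.
#'
#' @param features a \code{feature_table} or numeric matrix.
#' @param method linkage method passed to \code{\link[stats]{hclust}}.
#' @return List with the \code{hclust} tree, the leaf \code{order} (sample
#'   ids) and a \code{cut} helper is left to \code{\link[stats]{cutree}}.
#' @export
hierarchical_cluster <- function(features, method = "ward.D2") {
  m <- if (inherits(features, "feature_table")) features$features else
    as.matrix(features)
  if (nrow(m) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  m <- scale(m[, keep, drop = FALSE])
  if (anyNA(m)) {
    # pairwise-complete Euclidean distance, rescaled to full dimension
    p <- ncol(m)
    n <- nrow(m)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <-
        sqrt(sum((m[i, ok] - m[j, ok])^2) * p / max(sum(ok), 1))
    }
    dd <- stats::as.dist(d)
  } else {
    dd <- stats::dist(m)
  }
  tree <- stats::hclust(dd, method = method)
  tree$labels <- rownames(m)
  list(tree = tree, order = rownames(m)[tree$order])
}
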