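# Shared fixtures: tiny in-code tables and independent oracles.

# A minimal 3-sample table over the full core schema with benign values.
make_full_table <- function(fill = 1, n = 3, energy = TRUE) {
  sch <- panel_schema(energy = energy)
  p <- length(sch$metabolite_names)
  conc <- matrix(fill, n, p, dimnames = list(NULL, sch$metabolite_names))
  sample_table(conc, group = rep(c("control", "case"), length.out = n))
}

# Brute-force AUC over all positive-negative pairs (ties count half).
brute_force_auc <- function(scores, labels) {
  y <- as.integer(labels == sort(unique(labels))[2] | labels == TRUE)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Textbook BH: sort ascending, p * m / rank, running minimum from the tail,
# cap at 1, return in original order.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-feature toy cohort with a tunable class shift on log scale.
make_two_class_features <- function(n0 = 20, n1 = 20, shift = 3, seed = 42) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n0), rnorm(n0)),
    cbind(rnorm(n1, shift), rnorm(n1, shift))
  )
  colnames(X) <- c("f1", "f2")
  # group "1" sorts second and is therefore the positive class
  feature_table(X, group = rep(c("0", "1"), c(n0, n1)))
}
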