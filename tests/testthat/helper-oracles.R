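# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (loops, no shared code paths with
# the package internals) so tests compare two independent routes.

# random labeled expression matrix with no planted structure
random_lem <- function(seed, n_probes = 6, n_samples = 24,
                       classes = c("NT", "PT", "MT")) {
  set.seed(seed)
  k <- length(classes)
  counts <- rep(n_samples %/% k, k)
  counts[1] <- counts[1] + n_samples - sum(counts)
  labels <- rep(classes, times = counts)
  m <- matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  labeled_expression_matrix(m, labels, class_order = classes)
}

# MI estimator written out independently (no clamping shortcut sharing)
oracle_mi <- function(rho) {
  r2 <- min(rho^2, 1 - 1e-12)
  -0.5 * log(1 - r2)
}

oracle_cor <- function(x, y, method = "pearson") {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y, method = method)
}

# exhaustive per-step argmax of the mRMR score: at every step evaluate
# q = I(x_j, y) - mean_k I(x_j, x_k) for every remaining candidate by
# direct loops, and take the first maximum in input order
oracle_mrmr_rank <- function(lem, n_features, method = "pearson") {
  y <- as.integer(lem$labels) - 1
  p <- nrow(lem$values)
  rel <- sapply(seq_len(p), function(j)
    oracle_mi(oracle_cor(lem$values[j, ], y, method)))
  selected <- integer(0)
  for (step in seq_len(n_features)) {
    remaining <- setdiff(seq_len(p), selected)
    q <- sapply(remaining, function(j) {
      if (!length(selected)) return(rel[j])
      red <- sapply(selected, function(k)
        oracle_mi(oracle_cor(lem$values[j, ], lem$values[k, ], method)))
      rel[j] - mean(red)
    })
    selected <- c(selected, remaining[which.max(q)])
  }
  lem$probe_ids[selected]
}

# brute-force cosine distance (independent arithmetic)
oracle_cosine <- function(a, b)
  1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# Floyd-Warshall all-pairs shortest path lengths over an edge data.frame
# (protein1, protein2, combined_score) for either weight mode
oracle_all_pairs <- function(edges, weight_mode = "hop") {
  nodes <- sort(unique(c(edges$protein1, edges$protein2)))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  w <- if (weight_mode == "score") 1 - edges$combined_score / 1000
       else rep(1, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein1[i]; b <- edges$protein2[i]
    D[a, b] <- min(D[a, b], w[i])
    D[b, a] <- min(D[b, a], w[i])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# random scored graph for oracle comparisons
random_graph_edges <- function(seed, max_nodes = 20) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  prs <- combn(nodes, 2)
  take <- runif(ncol(prs)) < 0.25
  if (!any(take)) take[sample(ncol(prs), 3)] <- TRUE
  data.frame(protein1 = prs[1, take], protein2 = prs[2, take],
             combined_score = sample(1:1000, sum(take), replace = TRUE),
             stringsAsFactors = FALSE)
}
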