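#' Mutual information from a correlation coefficient
#'
#' Gaussian estimator of the mutual information between two variables from
#' their correlation coefficient: `I = -1/2 * log(1 - rho^2)` (in nats),
#' the MI of a bivariate Gaussian with correlation `rho`.  `rho^2` is
#' clamped at `1 - 1e-12` so perfectly correlated pairs give a large finite
#' value (about 13.8 nats) instead of infinity, keeping the mRMR score
#' finite and the greedy ordering well defined.
#'
#' @param rho numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Nonnegative MI values (nats), symmetric in the sign of `rho`
#'   and increasing in `|rho|`.
#' @examples
#' mutual_information(c(0, 0.5, 0.8))
#' @export
mutual_information <- function(rho) {
  if (!is.numeric(rho)) stop("'rho' must be numeric")
  if (any(abs(rho) > 1 + 1e-9, na.rm = TRUE))
    stop("|rho| > 1: not a correlation coefficient")
  rho2 <- pmin(rho^2, 1 - 1e-12)
  -0.5 * log1p(-rho2)
}

#' Correlation between a feature and the ordinal phase label
#'
#' Encodes the phenotype labels ordinally by their position in
#' `class_order` (`0, 1, 2, ...`) and returns the correlation between the
#' feature and that encoding.  A zero-variance feature returns exactly 0
#' (an undefined correlation must not poison the mRMR argmax).
#'
#' @param feature numeric vector, one value per sample.
#' @param labels per-sample labels.
#' @param class_order ordered vector of classes; defaults to the factor
#'   levels or order of first appearance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A single correlation coefficient in `[-1, 1]`.
#' @export
feature_label_correlation <- function(feature, labels, class_order = NULL,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(feature) < 3) stop("need at least 3 samples")
  if (length(feature) != length(labels))
    stop("feature and labels lengths differ")
  if (is.null(class_order))
    class_order <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  y <- match(as.character(labels), class_order) - 1L
  if (anyNA(y)) stop("labels not in class_order")
  if (length(unique(y)) < 2)
    stop("degenerate target: all samples have the same label")
  if (stats::sd(feature) == 0) return(0)
  stats::cor(feature, y, method = method)
}

#' mRMR score of a candidate probe
#'
#' The minimum-redundancy maximum-relevance score of a candidate feature
#' given an already-selected set `S`:
#' `q = I(x_j, y) - (1/|S|) * sum_{x_k in S} I(x_j, x_k)`,
#' with both relevance and redundancy measured by the correlation-based MI
#' estimator of [mutual_information()].  With an empty `S` the score is the
#' relevance alone.
#'
#' @param candidate a probe identifier present in `matrix`.
#' @param selected already-selected probes: a character vector of probe ids
#'   or a ranking from [mrmr_rank()] (its `probe_id` column is used).
#' @param matrix a [labeled_expression_matrix()].
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @return The scalar score `q`.
#' @export
mrmr_score <- function(candidate, selected, matrix,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "labeled_expression_matrix"))
  if (inherits(selected, "mrmr_ranking")) selected <- selected$probe_id
  selected <- as.character(selected)
  ids <- matrix$probe_ids
  if (!candidate %in% ids) stop("unknown probe id: ", candidate)
  unknown <- setdiff(selected, ids)
  if (length(unknown)) stop("unknown probe id: ", unknown[1])
  if (candidate %in% selected) stop("candidate already selected: ", candidate)

  x <- matrix$values[candidate, ]
  rel <- mutual_information(
    feature_label_correlation(x, matrix$labels, matrix$class_order, method))
  if (!length(selected)) return(rel)
  red <- vapply(selected, function(k) {
    mutual_information(safe_cor(x, matrix$values[k, ], method))
  }, numeric(1))
  rel - mean(red)
}

# correlation with the zero-variance convention (0, not NA)
safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y, method = method)
}

#' Rank probes by greedy mRMR selection
#'
#' Greedy minimum-redundancy maximum-relevance ranking: the first probe is
#' the one with maximal relevance `I(x, y)`; every later step adds the
#' probe maximizing `q = relevance - mean pairwise MI with the selected
#' set`.  Ties are broken by smallest probe index in input order, so the
#' ranking is deterministic.  Greedy selection nests: the first `k` entries
#' of a length-`n` ranking are the length-`k` ranking, which is what lets
#' incremental feature selection reuse prefixes of one ranking.
#'
#' @param matrix a [labeled_expression_matrix()].
#' @param n_features number of probes to rank (1..number of probes).
#' @param method correlation method for both relevance and redundancy,
#'   `"pearson"` (default) or `"spearman"`.
#' @return A data.frame of class `mrmr_ranking` with columns `step`,
#'   `probe_id`, `relevance`, `mean_redundancy` and `q` (`q = relevance -
#'   mean_redundancy`; the first step has `mean_redundancy = 0`).
#' @examples
#' sim <- simulate_expression_dataset(
#'   expression_sim_config(n_samples_per_class = c(A = 15, B = 15, C = 10),
#'                         n_null = 30, seed = 2))
#' head(mrmr_rank(sim$matrix, n_features = 6))
#' @export
mrmr_rank <- function(matrix, n_features,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "labeled_expression_matrix"))
  p <- nrow(matrix$values)
  if (n_features < 1 || n_features > p)
    stop("n_features must be between 1 and the number of probes (", p, ")")
  n_features <- as.integer(n_features)

  V <- t(matrix$values)                      # samples x probes
  y <- ordinal_labels(matrix)
  if (method == "spearman") {
    V <- apply(V, 2, rank)
    y <- rank(y)
  }
  sds <- apply(V, 2, stats::sd)
  const <- sds == 0
  rel_cor <- rep(0, p)
  if (stats::sd(y) > 0 && any(!const))
    rel_cor[!const] <- as.vector(stats::cor(V[, !const, drop = FALSE], y))
  relevance <- mutual_information(rel_cor)

  selected <- integer(n_features)
  red_sum <- rep(0, p)                        # running sum of MI vs selected
  available <- rep(TRUE, p)
  rel_out <- red_out <- q_out <- numeric(n_features)
  for (step in seq_len(n_features)) {
    n_sel <- step - 1L
    q <- if (n_sel == 0L) relevance else relevance - red_sum / n_sel
    q[!available] <- -Inf
    j <- which.max(q)                         # first max = input-order tie-break
    selected[step] <- j
    available[j] <- FALSE
    rel_out[step] <- relevance[j]
    red_out[step] <- if (n_sel == 0L) 0 else red_sum[j] / n_sel
    q_out[step] <- q[j]
    if (step < n_features) {
      rj <- rep(0, p)
      if (!const[j]) {
        ok <- !const
        rj[ok] <- as.vector(stats::cor(V[, ok, drop = FALSE], V[, j]))
      }
      red_sum <- red_sum + mutual_information(rj)
    }
  }
  structure(
    data.frame(step = seq_len(n_features),
               probe_id = matrix$probe_ids[selected],
               relevance = rel_out,
               mean_redundancy = red_out,
               q = q_out,
               stringsAsFactors = FALSE),
    class = c("mrmr_ranking", "data.frame"))
}
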