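#' Incremental feature selection over an mRMR ranking
#'
#' Sweeps the feature-set size `N = 1..max_n`, scoring the first `N` probes
#' of the ranking by jackknife validation for each requested prediction
#' engine.  Because greedy mRMR selection nests, the first `N` entries of
#' one ranking are exactly the mRMR solution of length `N`, so a single
#' ranking serves the whole sweep.  Besides the overall multiclass
#' accuracy, each point records the pairwise discrimination accuracy for
#' every unordered pair of phases (column `acc_<engine>_<A>_vs_<B>`).
#'
#' @param matrix a [labeled_expression_matrix()].
#' @param ranking an `mrmr_ranking` from [mrmr_rank()] (or a character
#'   vector of probe ids in rank order).
#' @param max_n sweep bound; defaults to `min(400, length(ranking))`,
#'   and must not exceed the ranking length.
#' @param engines prediction engines to evaluate (default all three).
#' @param select_engine engine whose accuracy defines the stored optimum
#'   (default `"nn1"`, the engine whose curve conventionally drives the
#'   selection); see [select_optimal()] to re-select with another engine.
#' @return An object of class `ifs_curve`: a list with `points` (data.frame
#'   with column `n`, per-engine `acc_<engine>` columns and pairwise
#'   columns), `ranking`, `engines`, `optimal_n`, `optimal_features`,
#'   `optimal_accuracy` and `selecting_engine`.
#' @examples
#' sim <- simulate_expression_dataset(
#'   expression_sim_config(n_samples_per_class = c(A = 12, B = 12, C = 8),
#'                         n_null = 10, seed = 4))
#' rk <- mrmr_rank(sim$matrix, 8)
#' curve <- run_ifs(sim$matrix, rk, max_n = 8, engines = "nn1")
#' curve$optimal_n
#' @export
run_ifs <- function(matrix, ranking, max_n = NULL,
                    engines = engine_ids(), select_engine = "nn1") {
  stopifnot(inherits(matrix, "labeled_expression_matrix"))
  engines <- match.arg(engines, engine_ids(), several.ok = TRUE)
  probes <- if (inherits(ranking, "mrmr_ranking")) ranking$probe_id
            else as.character(ranking)
  if (is.null(max_n)) max_n <- min(400L, length(probes))
  if (max_n < 1 || max_n > length(probes))
    stop("max_n must be between 1 and the ranking length (", length(probes), ")")
  if (!select_engine %in% engines)
    stop("select_engine '", select_engine, "' is not among the evaluated engines")

  labs <- as.character(matrix$labels)
  cls <- matrix$class_order
  pairs <- if (length(cls) >= 2) utils::combn(cls, 2, simplify = FALSE) else list()

  rows <- vector("list", max_n)
  for (N in seq_len(max_n)) {
    V <- t(matrix$values[probes[seq_len(N)], , drop = FALSE])
    pred <- jackknife_predict(V, labs, cls, engines)
    rec <- list(n = N)
    for (e in engines) {
      rec[[paste0("acc_", e)]] <- mean(pred[[e]] == labs)
      for (pr in pairs) {
        keep <- labs %in% pr
        rec[[paste0("acc_", e, "_", pr[1], "_vs_", pr[2])]] <-
          mean(pred[[e]][keep] == labs[keep])
      }
    }
    rows[[N]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  points <- do.call(rbind, rows)

  curve <- structure(
    list(points = points, ranking = probes[seq_len(max_n)],
         engines = engines),
    class = "ifs_curve")
  opt <- select_optimal(curve, select_engine)
  curve$optimal_n <- opt$optimal_n
  curve$optimal_features <- opt$optimal_features
  curve$optimal_accuracy <- opt$accuracy
  curve$selecting_engine <- select_engine
  curve
}

#' Select the optimal feature count from an IFS curve
#'
#' Applies the "best accuracy, smallest feature number" rule: the smallest
#' `N` attaining the maximum jackknife accuracy of the chosen engine.
#'
#' @param curve an `ifs_curve` from [run_ifs()].
#' @param engine engine whose accuracy column drives the rule.
#' @return A list with `optimal_n`, `optimal_features` (the first
#'   `optimal_n` ranked probes) and `accuracy` (the maximum attained).
#' @export
select_optimal <- function(curve, engine = "nn1") {
  stopifnot(inherits(curve, "ifs_curve"))
  col <- paste0("acc_", engine)
  if (!col %in% names(curve$points))
    stop("engine '", engine, "' was not evaluated in this curve")
  acc <- curve$points[[col]]
  best <- max(acc)
  n_opt <- curve$points$n[which(acc == best)[1]]   # smallest N at the max
  list(optimal_n = n_opt,
       optimal_features = curve$ranking[seq_len(n_opt)],
       accuracy = best)
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("IFS curve: N = 1..", max(x$points$n), ", engines: ",
      paste(x$engines, collapse = ", "), "\n", sep = "")
  if (!is.null(x$optimal_n))
    cat("Optimum (", x$selecting_engine, "): N = ", x$optimal_n,
        ", accuracy = ", format(x$optimal_accuracy, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot an IFS curve
#'
#' Accuracy of each prediction engine as a function of the number of
#' top-ranked features, with the selected optimum marked.
#'
#' @param x an `ifs_curve`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  cols_acc <- paste0("acc_", x$engines)
  graphics::matplot(x$points$n, as.matrix(x$points[cols_acc]),
                    type = "l", lty = 1, lwd = 2,
                    xlab = "Number of features (N)",
                    ylab = "Jackknife accuracy",
                    col = seq_along(cols_acc), ...)
  graphics::legend("bottomright", legend = x$engines, lty = 1, lwd = 2,
                   col = seq_along(cols_acc), bty = "n")
  if (!is.null(x$optimal_n))
    graphics::abline(v = x$optimal_n, lty = 3)
  invisible(x)
}
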