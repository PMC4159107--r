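#' Cosine distance between two samples
#'
#' Distance between two expression profiles over a common feature set:
#' `d = 1 - (e1 . e2) / (||e1|| ||e2||)`, i.e. one minus the cosine of the
#' angle between the vectors.  The distance lies in `[0, 2]`, is symmetric,
#' and is invariant to positive rescaling of either vector.
#'
#' @param e1,e2 numeric vectors of equal length with nonzero norm.
#' @return The cosine distance, a scalar in `[0, 2]`.
#' @examples
#' sample_distance(c(1, 2), c(3, 6))  # 0: same direction
#' sample_distance(c(1, 0), c(0, 1))  # 1: orthogonal
#' @export
sample_distance <- function(e1, e2) {
  if (length(e1) != length(e2))
    stop("feature vectors have different lengths (", length(e1), " vs ",
         length(e2), ")")
  if (length(e1) < 1) stop("feature vectors must be nonempty")
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm feature vector")
  d <- 1 - sum(e1 * e2) / (n1 * n2)
  min(max(d, 0), 2)
}

engine_ids <- function() c("vote5", "nn1", "centroid")

check_train <- function(train_values, train_labels) {
  if (!is.matrix(train_values) || nrow(train_values) < 1)
    stop("no reference samples: training set is empty")
  if (nrow(train_values) != length(train_labels))
    stop("training labels do not match the number of training samples")
}

#' Nearest-neighbor prediction (1-NN)
#'
#' Predicts the label of `query` as the label of the training sample at
#' minimal cosine distance.  Distance ties are broken by the smallest
#' training index.
#'
#' @param train_values numeric matrix, training samples in rows.
#' @param train_labels per-row training labels.
#' @param query numeric feature vector.
#' @return The predicted label (same type as `train_labels` entries).
#' @export
predict_nn1 <- function(train_values, train_labels, query) {
  check_train(train_values, train_labels)
  d <- apply(train_values, 1, sample_distance, e2 = query)
  as.character(train_labels)[which.min(d)]
}

#' Five-nearest-neighbor vote prediction
#'
#' Predicts the most frequent label among the five nearest training
#' samples under the cosine distance.  If fewer than five training samples
#' exist, the neighborhood is truncated to the training size (with a
#' warning).  Vote ties are resolved in favor of the tied label whose
#' nearest representative is closest to the query.
#'
#' @inheritParams predict_nn1
#' @return The predicted label.
#' @export
predict_vote5 <- function(train_values, train_labels, query) {
  check_train(train_values, train_labels)
  d <- apply(train_values, 1, sample_distance, e2 = query)
  k <- 5L
  if (nrow(train_values) < k) {
    k <- nrow(train_values)
    warning("fewer than 5 training samples; vote truncated to k = ", k)
  }
  nbr <- order(d)[seq_len(k)]                 # stable: index breaks distance ties
  vote_majority(as.character(train_labels)[nbr])
}

# majority of labels ordered by proximity; ties -> label of the nearest
# member of a tied class
vote_majority <- function(nbr_labels) {
  counts <- table(nbr_labels)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1L) return(tied)
  nbr_labels[nbr_labels %in% tied][1L]
}

#' Nearest-centroid prediction
#'
#' Computes the arithmetic mean expression vector of each class present in
#' the training set and predicts the label of the centroid at minimal
#' cosine distance from the query.  Distance ties go to the earlier class
#' in `class_order`.
#'
#' @inheritParams predict_nn1
#' @param class_order ordered class vector; defaults to factor levels or
#'   order of first appearance in `train_labels`.
#' @return The predicted label.
#' @export
predict_centroid <- function(train_values, train_labels, query,
                             class_order = NULL) {
  check_train(train_values, train_labels)
  if (is.null(class_order))
    class_order <- if (is.factor(train_labels)) levels(train_labels)
                   else unique(as.character(train_labels))
  train_labels <- as.character(train_labels)
  present <- class_order[class_order %in% train_labels]
  d <- vapply(present, function(cl) {
    ctr <- colMeans(train_values[train_labels == cl, , drop = FALSE])
    sample_distance(ctr, query)
  }, numeric(1))
  present[which.min(d)]                       # first min = class_order tie-break
}

#' Jackknife (leave-one-out) validation of a prediction engine
#'
#' Scores a feature subset by leave-one-out validation: each sample's
#' phenotype is predicted from the remaining samples only.  The held-out
#' sample is excluded from the neighbor pool and from centroid
#' computation.  If leaving a sample out empties its class, the centroid
#' engine omits that class's centroid for that fold (with a warning).
#'
#' @param matrix a [labeled_expression_matrix()] with at least 2 samples.
#' @param feature_subset nonempty vector of probe ids to use.
#' @param engine one of `"vote5"`, `"nn1"`, `"centroid"`, or a vector of
#'   them (default: all three).
#' @return A list with elements `predictions` (data.frame: `sample_id`,
#'   `true`, one predicted-label column per engine, and one
#'   `correct_<engine>` indicator column per engine) and `accuracy`
#'   (named vector: fraction of correct predictions per engine).
#' @examples
#' sim <- simulate_expression_dataset(
#'   expression_sim_config(n_samples_per_class = c(A = 12, B = 12, C = 8),
#'                         effect_size = 5, n_null = 5, seed = 3))
#' inf <- sim$truth$probe_id[sim$truth$role == "informative"]
#' jackknife(sim$matrix, inf, engine = "nn1")$accuracy
#' @export
jackknife <- function(matrix, feature_subset, engine = engine_ids()) {
  stopifnot(inherits(matrix, "labeled_expression_matrix"))
  engine <- match.arg(engine, engine_ids(), several.ok = TRUE)
  if (!length(feature_subset)) stop("feature_subset must be nonempty")
  missing_p <- setdiff(feature_subset, matrix$probe_ids)
  if (length(missing_p)) stop("unknown probe id: ", missing_p[1])
  n <- ncol(matrix$values)
  if (n < 2) stop("jackknife needs at least 2 samples")

  V <- t(matrix$values[feature_subset, , drop = FALSE])  # samples x features
  labs <- as.character(matrix$labels)
  pred <- jackknife_predict(V, labs, matrix$class_order, engine)

  out <- data.frame(sample_id = matrix$sample_ids, true = labs,
                    stringsAsFactors = FALSE)
  acc <- numeric(0)
  for (e in engine) {
    out[[e]] <- pred[[e]]
    out[[paste0("correct_", e)]] <- pred[[e]] == labs
    acc[e] <- mean(pred[[e]] == labs)
  }
  list(predictions = out, accuracy = acc)
}

# vectorized leave-one-out prediction core shared by jackknife() and
# run_ifs(); V is samples x features
jackknife_predict <- function(V, labs, class_order, engines) {
  n <- nrow(V)
  norms <- sqrt(rowSums(V^2))
  if (any(norms == 0)) stop("zero-norm feature vector for sample ",
                            which(norms == 0)[1])
  Vn <- V / norms
  res <- list()
  if (any(engines %in% c("nn1", "vote5"))) {
    D <- 1 - tcrossprod(Vn)
    diag(D) <- Inf
    if ("nn1" %in% engines)
      res$nn1 <- labs[apply(D, 1, which.min)]
    if ("vote5" %in% engines) {
      k <- min(5L, n - 1L)
      if (k < 5L) warning("fewer than 5 reference samples; vote truncated to k = ", k)
      res$vote5 <- vapply(seq_len(n), function(i) {
        nbr <- order(D[i, ])[seq_len(k)]
        vote_majority(labs[nbr])
      }, character(1))
    }
  }
  if ("centroid" %in% engines) {
    present <- class_order[class_order %in% labs]
    sums <- do.call(rbind, lapply(present, function(cl)
      colSums(V[labs == cl, , drop = FALSE])))   # classes x features
    cnts <- vapply(present, function(cl) sum(labs == cl), integer(1))
    warned <- FALSE
    res$centroid <- vapply(seq_len(n), function(i) {
      d <- rep(Inf, length(present))
      for (ci in seq_along(present)) {
        m <- cnts[ci] - (labs[i] == present[ci])
        if (m == 0L) {
          if (!warned) {
            warning("leaving sample out empties class '", present[ci],
                    "'; centroid omitted for that fold")
            warned <<- TRUE
          }
          next
        }
        ctr <- (sums[ci, ] - if (labs[i] == present[ci]) V[i, ] else 0) / m
        d[ci] <- sample_distance(ctr, V[i, ])
      }
      present[which.min(d)]
    }, character(1))
  }
  res[engines]
}

#' Confusion counts for a designated positive class
#'
#' Binarizes multiclass predictions against one positive class and counts
#' true/false positives and negatives.
#'
#' @param true,predicted label vectors of equal length.
#' @param positive the class treated as positive.
#' @return A named list `TP`, `TN`, `FP`, `FN` (sums to the number of
#'   samples).
#' @export
confusion_counts <- function(true, predicted, positive) {
  if (length(true) != length(predicted))
    stop("true and predicted lengths differ")
  tp <- sum(true == positive & predicted == positive)
  tn <- sum(true != positive & predicted != positive)
  fp <- sum(true != positive & predicted == positive)
  fn <- sum(true == positive & predicted != positive)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Classification accuracy from confusion counts
#'
#' `Accuracy = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a list or vector with elements `TP`, `TN`, `FP`, `FN`,
#'   e.g. from [confusion_counts()].
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop("empty evaluation: no scored samples")
  (counts$TP + counts$TN) / tot
}

#' Pairwise phase-discrimination accuracy
#'
#' Restricts jackknife predictions to the samples whose true label is one
#' of two given classes and returns the fraction predicted exactly right
#' on that restricted set.  This is the two-phase discrimination accuracy
#' (e.g. normal vs metastatic) extracted from a three-class prediction.
#'
#' @param predictions the `predictions` data.frame from [jackknife()].
#' @param engine engine column to score.
#' @param class_a,class_b the two classes defining the restriction.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_accuracy <- function(predictions, engine, class_a, class_b) {
  engine <- match.arg(engine, engine_ids())
  keep <- predictions$true %in% c(class_a, class_b)
  if (!any(keep)) stop("empty evaluation: no samples with true label in {",
                       class_a, ", ", class_b, "}")
  mean(predictions[[engine]][keep] == predictions$true[keep])
}
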