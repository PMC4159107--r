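#' Labeled expression matrix
#'
#' Container for a probes-by-samples expression table together with a
#' phenotype label per sample.  The label is treated as an ordered phase
#' (e.g. normal tissue < primary tumor < metastatic tumor): `class_order`
#' fixes the ordinal encoding `0, 1, 2, ...` used by the correlation-based
#' mutual-information estimator.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#'   Row names are probe identifiers, column names sample identifiers.
#' @param labels character or factor vector of per-sample phenotype labels,
#'   one per column of `values`.
#' @param class_order character vector giving the phase ordering; every
#'   label must occur in it.  Defaults to the order of first appearance.
#' @return An object of class `labeled_expression_matrix`: a list with
#'   elements `values`, `probe_ids`, `sample_ids`, `labels` (a factor with
#'   levels `class_order`) and `class_order`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' lem <- labeled_expression_matrix(m, c("NT", "NT", "PT", "MT"),
#'                                  class_order = c("NT", "PT", "MT"))
#' @export
labeled_expression_matrix <- function(values, labels, class_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (probes x samples)")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe_%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (length(labels) != ncol(values))
    stop("length(labels) [", length(labels),
         "] must equal the number of samples [", ncol(values), "]")
  labels <- as.character(labels)
  if (is.null(class_order)) class_order <- unique(labels)
  missing_cls <- setdiff(labels, class_order)
  if (length(missing_cls))
    stop("labels not in class_order: ", paste(unique(missing_cls), collapse = ", "))
  if (anyNA(values))
    stop("'values' contains missing values; drop or impute before construction")
  structure(
    list(values = values,
         probe_ids = rownames(values),
         sample_ids = colnames(values),
         labels = factor(labels, levels = class_order),
         class_order = class_order),
    class = "labeled_expression_matrix")
}

#' @export
print.labeled_expression_matrix <- function(x, ...) {
  cat("Labeled expression matrix:", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  cat("Classes (", paste(x$class_order, collapse = " < "), "):",
      paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.labeled_expression_matrix <- function(x) dim(x$values)

# ordinal encoding of the phase labels: first class -> 0, second -> 1, ...
ordinal_labels <- function(lem) as.integer(lem$labels) - 1L
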