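#' Read an expression matrix and its phenotype labels
#'
#' Reads a probes-in-rows TSV (first column probe ids, header row of
#' sample ids — GEO series-matrix orientation) and a two-column labels TSV
#' (`sample_id`, `label`, with header).  Samples are aligned to the
#' intersection of the two files, in expression-header order; samples
#' present only in the labels file are ignored with a warning, while
#' expression samples without a label are an error.  Probes containing
#' any missing value are dropped with a message.
#'
#' @param path expression TSV path.
#' @param labels_path labels TSV path.
#' @param class_order ordered class vector; defaults to order of first
#'   appearance in the labels file.
#' @return A [labeled_expression_matrix()].
#' @export
read_expression <- function(path, labels_path, class_order = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a probe column plus samples")
  probe_ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  for (j in seq_len(ncol(tab))) {
    col <- tab[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))[1]
      if (!is.na(bad))
        stop("non-numeric cell at probe '", probe_ids[bad], "', sample '",
             names(tab)[j], "': '", col[bad], "'")
      tab[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(tab)
  rownames(values) <- probe_ids
  if (nrow(values) > ncol(values) * 50 && ncol(values) <= 3)
    stop("input looks transposed (", nrow(values), " rows x ", ncol(values),
         " columns); expected probes in rows with one column per sample")

  lab_tab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (ncol(lab_tab) < 2) stop("labels file needs columns sample_id, label")
  lab_map <- stats::setNames(as.character(lab_tab[[2]]),
                             as.character(lab_tab[[1]]))
  extra <- setdiff(names(lab_map), colnames(values))
  if (length(extra))
    warning("labels for samples absent from expression ignored: ",
            paste(extra, collapse = ", "))
  unmapped <- setdiff(colnames(values), names(lab_map))
  if (length(unmapped))
    stop("expression samples without a label: ",
         paste(unmapped, collapse = ", "))

  drop <- rowSums(is.na(values)) > 0
  if (any(drop)) {
    message("dropped ", sum(drop), " probe(s) with missing values")
    values <- values[!drop, , drop = FALSE]
  }
  labels <- unname(lab_map[colnames(values)])
  if (is.null(class_order)) class_order <- unique(as.character(lab_tab[[2]]))
  labeled_expression_matrix(values, labels, class_order)
}

#' Write an expression dataset as TSV files
#'
#' Writes the expression matrix (probes in rows, `probe_id` first column,
#' sample-id header), the labels table (`sample_id`, `label`) and, when
#' present, the ground-truth probe-role sidecar from the simulator.
#'
#' @param sim either a [labeled_expression_matrix()] or the list returned
#'   by [simulate_expression_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_expression_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lem <- if (inherits(sim, "labeled_expression_matrix")) sim else sim$matrix
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"))
  expr <- data.frame(probe_id = lem$probe_ids, lem$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = lem$sample_ids, label = as.character(lem$labels)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!inherits(sim, "labeled_expression_matrix") && !is.null(sim$truth)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Write an interaction graph in STRING flat-file convention
#'
#' Three whitespace-separated columns: `protein1 protein2 combined_score`,
#' with header, scores as integers.
#'
#' @param graph an [interaction_graph()].
#' @param path output file.
#' @export
write_interactions <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  out <- graph$edges
  out$combined_score <- as.integer(round(out$combined_score))
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene identifier mapping table
#'
#' Two-column TSV (`probe_id`, `gene_id`, header optional) mapping array
#' probes to gene/protein identifiers used by the interaction network.
#'
#' @param path mapping TSV path.
#' @return Named character vector: `gene_id` values named by `probe_id`.
#' @export
read_id_mapping <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           header = FALSE, col.names = c("probe_id", "gene_id"))
  if (identical(tolower(tab$probe_id[1]), "probe_id")) tab <- tab[-1, ]
  stats::setNames(as.character(tab$gene_id), as.character(tab$probe_id))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
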