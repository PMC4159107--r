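#' Scored interaction graph
#'
#' Undirected protein/gene interaction graph in the STRING flat-file
#' convention: each edge carries an integer `combined_score` in
#' `[0, 1000]`.  Self-loops are dropped; duplicate pairs are collapsed to
#' their maximum score.  `weight_mode` controls shortest-path weighting:
#' `"hop"` counts edges, `"score"` uses `1 - combined_score/1000` so that
#' high-confidence interactions are cheaper to traverse.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param weight_mode `"hop"` (default) or `"score"`.
#' @return An object of class `interaction_graph`: list with `edges`
#'   (normalized data.frame), `nodes` (sorted identifiers) and
#'   `weight_mode`.
#' @export
interaction_graph <- function(edges, weight_mode = c("hop", "score")) {
  weight_mode <- match.arg(weight_mode)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edges)))
    stop("edges must have columns protein1, protein2, combined_score")
  edges$protein1 <- as.character(edges$protein1)
  edges$protein2 <- as.character(edges$protein2)
  if (any(edges$combined_score < 0 | edges$combined_score > 1000))
    stop("combined_score outside [0, 1000]")
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$combined_score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    edges <- data.frame(protein1 = vapply(parts, `[`, "", 1),
                        protein2 = vapply(parts, `[`, "", 2),
                        combined_score = as.numeric(score),
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$protein1, edges$protein2))),
                 weight_mode = weight_mode),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (weight mode:", x$weight_mode, ")\n")
  invisible(x)
}

#' Load a STRING-convention interaction file
#'
#' Reads a whitespace-separated three-column edge list (`protein1
#' protein2 combined_score`, optional header line), drops edges scoring
#' below `score_threshold`, and collapses duplicates to the maximum score.
#'
#' @param edge_file path to the edge list.
#' @param score_threshold minimum combined score retained; the default 400
#'   is the STRING "medium confidence" cutoff.
#' @param weight_mode passed to [interaction_graph()].
#' @return An [interaction_graph()].
#' @export
load_interactions <- function(edge_file, score_threshold = 400,
                              weight_mode = c("hop", "score")) {
  weight_mode <- match.arg(weight_mode)
  if (score_threshold < 0) stop("score_threshold must be nonnegative")
  lines <- readLines(edge_file)
  start <- 1L
  if (length(lines)) {
    first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
    if (length(first) == 3 && is.na(suppressWarnings(as.numeric(first[3]))))
      start <- 2L                             # header line
  }
  keep <- which(nzchar(trimws(lines)))
  keep <- keep[keep >= start]
  recs <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 3)
      stop("malformed line ", i, " in ", edge_file, ": expected 3 fields, got ",
           length(f))
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s))
      stop("malformed line ", i, " in ", edge_file, ": non-numeric score '",
           f[3], "'")
    list(f[1], f[2], s)
  })
  edges <- data.frame(
    protein1 = vapply(recs, function(r) r[[1]], ""),
    protein2 = vapply(recs, function(r) r[[2]], ""),
    combined_score = vapply(recs, function(r) r[[3]], numeric(1)),
    stringsAsFactors = FALSE)
  edges <- edges[edges$combined_score >= score_threshold, , drop = FALSE]
  interaction_graph(edges, weight_mode)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes)
  if (graph$weight_mode == "score")
    igraph::E(g)$weight <- 1 - graph$edges$combined_score / 1000
  g
}

graph_weights <- function(graph) {
  if (graph$weight_mode == "score") 1 - graph$edges$combined_score / 1000
  else rep(1, nrow(graph$edges))
}

#' Shortest path between two genes
#'
#' Minimum-total-weight path under the graph's `weight_mode` (`"hop"`:
#' every edge counts 1; `"score"`: edge weight `1 - combined_score/1000`).
#' Among equal-weight shortest paths the lexicographically smallest node
#' sequence is returned, so the result is deterministic.
#'
#' @param graph an [interaction_graph()].
#' @param source,target node identifiers present in the graph.
#' @return A list with `path` (node sequence, `NULL` if disconnected),
#'   `length` (total weight, `Inf` if disconnected) and `reachable`.
#' @export
shortest_path <- function(graph, source, target) {
  stopifnot(inherits(graph, "interaction_graph"))
  for (v in c(source, target))
    if (!v %in% graph$nodes) stop("node not in graph: ", v)
  if (source == target)
    return(list(path = source, length = 0, reachable = TRUE))
  g <- as_igraph(graph)
  w <- if (graph$weight_mode == "score") NULL else NA  # NA: ignore weights
  ds <- as.vector(igraph::distances(g, v = source, weights = w))
  names(ds) <- igraph::V(g)$name
  if (!is.finite(ds[target]))
    return(list(path = NULL, length = Inf, reachable = FALSE))
  dt <- as.vector(igraph::distances(g, v = target, weights = w))
  names(dt) <- igraph::V(g)$name

  # walk from source, always taking the smallest-id unvisited neighbor that
  # stays on some shortest path: yields the lexicographically smallest
  # optimum among simple paths (visited-exclusion keeps the walk finite
  # even across zero-weight edges)
  ew <- graph_weights(graph)
  nbrs <- split(c(graph$edges$protein2, graph$edges$protein1),
                c(graph$edges$protein1, graph$edges$protein2))
  wts <- split(c(ew, ew), c(graph$edges$protein1, graph$edges$protein2))
  total <- ds[target]
  path <- source
  cur <- source
  tol <- 1e-9
  while (cur != target) {
    cand <- nbrs[[cur]]
    ok <- abs(ds[cur] + wts[[cur]] + dt[cand] - total) < tol &
      !(cand %in% path)
    if (!any(ok)) {
      # zero-weight plateaus can strand the greedy simple walk; fall back
      # to the (deterministic) library path
      vp <- igraph::shortest_paths(g, from = source, to = target,
                                   weights = w)$vpath[[1]]
      return(list(path = igraph::V(g)$name[vp],
                  length = unname(ds[target]), reachable = TRUE))
    }
    nxt <- sort(cand[ok])[1]
    path <- c(path, nxt)
    cur <- nxt
  }
  list(path = unname(path), length = unname(ds[target]), reachable = TRUE)
}

#' Shortest-path sub-network among seed genes
#'
#' Computes the shortest path between every unordered pair of seed genes
#' and returns the union of all path nodes and edges.  Non-seed nodes on
#' these paths are the bridging genes: interaction partners that connect
#' the selected surrogates in the background network.  Seed genes missing
#' from the graph, or pairs with no connecting path, are reported in
#' `unresolved_pairs` (with a warning), not treated as fatal.
#'
#' @param graph an [interaction_graph()].
#' @param seed_genes at least two node identifiers.
#' @param all_shortest if `TRUE`, union every equal-weight shortest path
#'   per pair instead of the single deterministic one.
#' @return An object of class `subnetwork_result`: list with `seed_genes`,
#'   `paths` (data.frame: `from`, `to`, `length`, `path` as "A->B->C"),
#'   `nodes` (data.frame: `node`, `role` seed/bridge), `edges` (data.frame
#'   with scores), `bridge_genes`, `unresolved_pairs`.
#' @export
build_subnetwork <- function(graph, seed_genes, all_shortest = FALSE) {
  stopifnot(inherits(graph, "interaction_graph"))
  seed_genes <- unique(as.character(seed_genes))
  if (length(seed_genes) < 2) stop("need at least 2 seed genes")
  present <- seed_genes[seed_genes %in% graph$nodes]
  absent <- setdiff(seed_genes, present)
  if (length(absent))
    warning("seed genes absent from graph: ", paste(absent, collapse = ", "))
  if (length(present) < 2)
    stop("fewer than 2 seed genes present in the graph")

  g <- if (all_shortest) as_igraph(graph) else NULL
  w <- if (graph$weight_mode == "score") NULL else NA
  prs <- utils::combn(sort(present), 2, simplify = FALSE)
  unresolved <- data.frame(from = character(0), to = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  for (a in absent)
    for (b in setdiff(seed_genes, a))
      if (a < b || !(b %in% absent))
        unresolved <- rbind(unresolved,
                            data.frame(from = min(a, b), to = max(a, b),
                                       reason = "missing endpoint"))
  path_rows <- list()
  node_set <- character(0)
  edge_keys <- character(0)
  add_path <- function(p) {
    node_set <<- union(node_set, p)
    if (length(p) > 1) {
      a <- p[-length(p)]; b <- p[-1]
      edge_keys <<- union(edge_keys,
                          paste(pmin(a, b), pmax(a, b), sep = "\r"))
    }
  }
  for (pr in prs) {
    sp <- shortest_path(graph, pr[1], pr[2])
    if (!sp$reachable) {
      warning("no path between seed genes ", pr[1], " and ", pr[2])
      unresolved <- rbind(unresolved,
                          data.frame(from = pr[1], to = pr[2],
                                     reason = "disconnected"))
      next
    }
    path_rows[[length(path_rows) + 1L]] <-
      data.frame(from = pr[1], to = pr[2], length = sp$length,
                 path = paste(sp$path, collapse = "->"),
                 stringsAsFactors = FALSE)
    if (all_shortest) {
      asp <- igraph::all_shortest_paths(g, from = pr[1], to = pr[2],
                                        weights = w)$vpaths
      for (vp in asp) add_path(igraph::V(g)$name[vp])
    } else add_path(sp$path)
  }
  nodes <- sort(node_set)
  edges <- graph$edges[paste(graph$edges$protein1, graph$edges$protein2,
                             sep = "\r") %in% edge_keys, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(seed_genes = seed_genes,
         paths = if (length(path_rows)) do.call(rbind, path_rows)
                 else data.frame(from = character(0), to = character(0),
                                 length = numeric(0), path = character(0)),
         nodes = data.frame(node = nodes,
                            role = ifelse(nodes %in% seed_genes,
                                          "seed", "bridge"),
                            stringsAsFactors = FALSE),
         edges = edges,
         bridge_genes = setdiff(nodes, seed_genes),
         unresolved_pairs = unresolved),
    class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat("Shortest-path sub-network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("Seed genes:", paste(x$seed_genes, collapse = ", "), "\n")
  cat("Bridge genes:", if (length(x$bridge_genes))
      paste(x$bridge_genes, collapse = ", ") else "(none)", "\n")
  if (nrow(x$unresolved_pairs))
    cat("Unresolved pairs:", nrow(x$unresolved_pairs), "\n")
  invisible(x)
}
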