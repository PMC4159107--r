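#' Configuration for the synthetic interaction-graph generator
#'
#' Describes a scored random interaction network with planted ground
#' truth: an Erdős–Rényi background among background nodes, a set of seed
#' genes, and planted bridge paths joining seed pairs through declared
#' bridge nodes.  Background edges never touch seed or bridge nodes, so
#' the planted paths are guaranteed to be the only routes between seeds
#' and the planted bridge set is an exact ground truth for
#' [build_subnetwork()].
#'
#' @param n_background_nodes number of background nodes (named `BG001`,
#'   `BG002`, ...).
#' @param edge_probability Erdős–Rényi edge probability among background
#'   nodes, in `[0, 1]`.
#' @param seed_genes character vector of seed gene identifiers.
#' @param planted_bridges list of planted paths; each element is a list
#'   with `pair = c(seedA, seedB)` and `bridge = c(...)` (possibly empty:
#'   a direct seed-seed edge).  Both endpoints must be declared in
#'   `seed_genes`.
#' @param score_range integer combined-score range `c(min, max)` within
#'   `[0, 1000]`; background edges draw scores uniformly in the range,
#'   planted edges get the maximum.
#' @param seed integer random seed.
#' @return A list of class `graph_sim_config`.
#' @export
graph_sim_config <- function(n_background_nodes = 30,
                             edge_probability = 0.1,
                             seed_genes = character(0),
                             planted_bridges = list(),
                             score_range = c(400, 1000),
                             seed = 1L) {
  if (edge_probability < 0 || edge_probability > 1)
    stop("edge_probability must be in [0, 1]")
  if (n_background_nodes < 0) stop("n_background_nodes must be >= 0")
  if (any(score_range < 0) || any(score_range > 1000) ||
      score_range[1] > score_range[2])
    stop("score_range must be an increasing pair within [0, 1000]")
  seed_genes <- as.character(seed_genes)
  for (pb in planted_bridges) {
    if (!all(c("pair", "bridge") %in% names(pb)) || length(pb$pair) != 2)
      stop("each planted bridge needs a 2-element 'pair' and a 'bridge' vector")
    if (!all(pb$pair %in% seed_genes))
      stop("planted bridge endpoints must be declared seed genes: ",
           paste(setdiff(pb$pair, seed_genes), collapse = ", "))
  }
  structure(
    list(n_background_nodes = as.integer(n_background_nodes),
         edge_probability = edge_probability,
         seed_genes = seed_genes,
         planted_bridges = planted_bridges,
         score_range = score_range,
         seed = as.integer(seed)),
    class = "graph_sim_config")
}

#' Simulate a scored interaction graph with planted bridge paths
#'
#' Generates the network described by [graph_sim_config()]: Erdős–Rényi
#' background edges (uniform scores in `score_range`) plus the planted
#' bridge paths (maximum score).  The union of bridge nodes over all
#' planted paths is returned as ground truth.
#'
#' @param config a [graph_sim_config()].
#' @return A list with `graph` (an [interaction_graph()]),
#'   `bridge_nodes` (ground-truth bridging genes) and `config`.
#' @examples
#' cfg <- graph_sim_config(
#'   n_background_nodes = 10, edge_probability = 0.2,
#'   seed_genes = c("GENE_A", "GENE_B"),
#'   planted_bridges = list(list(pair = c("GENE_A", "GENE_B"),
#'                               bridge = "LINKER1")),
#'   seed = 5)
#' sim <- simulate_interaction_graph(cfg)
#' sim$bridge_nodes
#' @export
simulate_interaction_graph <- function(config) {
  stopifnot(inherits(config, "graph_sim_config"))
  set.seed(config$seed)
  bg <- if (config$n_background_nodes > 0)
          sprintf("BG%03d", seq_len(config$n_background_nodes)) else character(0)

  edges <- data.frame(protein1 = character(0), protein2 = character(0),
                      combined_score = numeric(0), stringsAsFactors = FALSE)
  if (length(bg) >= 2 && config$edge_probability > 0) {
    prs <- utils::combn(bg, 2)
    take <- stats::runif(ncol(prs)) < config$edge_probability
    if (any(take)) {
      sc <- sample(seq(config$score_range[1], config$score_range[2]),
                   sum(take), replace = TRUE)
      edges <- data.frame(protein1 = prs[1, take], protein2 = prs[2, take],
                          combined_score = sc, stringsAsFactors = FALSE)
    }
  }
  bridge_nodes <- character(0)
  for (pb in config$planted_bridges) {
    chain <- c(pb$pair[1], pb$bridge, pb$pair[2])
    bridge_nodes <- union(bridge_nodes, pb$bridge)
    edges <- rbind(edges,
                   data.frame(protein1 = chain[-length(chain)],
                              protein2 = chain[-1],
                              combined_score = config$score_range[2],
                              stringsAsFactors = FALSE))
  }
  list(graph = interaction_graph(edges),
       bridge_nodes = sort(bridge_nodes),
       config = config)
}
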