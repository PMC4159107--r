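string_file <- function(lines, header = TRUE) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(c(if (header) "protein1 protein2 combined_score", lines), f)
  f
}

test_that("interaction files are parsed with STRING conventions", {
  f <- string_file(c("A B 300", "B A 700", "B C 500", "C C 900"))
  g <- load_interactions(f, score_threshold = 0)
  # duplicate A-B collapsed to max score, self-loop dropped
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$combined_score[g$edges$protein1 == "A"], 700)

  expect_equal(nrow(load_interactions(f, score_threshold = 950)$edges), 0)

  f2 <- string_file(c("A B 10", "A C 20", "B C 30", "A B 15"))
  expect_equal(nrow(load_interactions(f2, 0)$edges), 3)  # distinct pairs

  f3 <- string_file(c("A B 10", "A C"))
  expect_error(load_interactions(f3, 0), "line 3")
  f4 <- string_file(c("A B ten"))
  expect_error(load_interactions(f4, 0), "non-numeric score")
  expect_error(load_interactions(f2, -5), "nonnegative")
})

test_that("graph construction validates scores and normalizes pairs", {
  expect_error(interaction_graph(
    data.frame(protein1 = "A", protein2 = "B", combined_score = 1200)),
    "\\[0, 1000\\]")
  g <- interaction_graph(data.frame(protein1 = c("B", "A"),
                                    protein2 = c("A", "C"),
                                    combined_score = c(10, 20)))
  expect_identical(g$edges$protein1, c("A", "A"))
  expect_identical(g$nodes, c("A", "B", "C"))
})

test_that("shortest paths are found, deterministic, and report disconnection", {
  g <- interaction_graph(data.frame(
    protein1 = c("A", "B", "X"), protein2 = c("B", "C", "Y"),
    combined_score = c(500, 500, 500)))
  expect_equal(shortest_path(g, "A", "A"), list(path = "A", length = 0,
                                                reachable = TRUE))
  sp <- shortest_path(g, "A", "C")
  expect_identical(sp$path, c("A", "B", "C"))
  expect_equal(sp$length, 2)
  expect_false(shortest_path(g, "A", "X")$reachable)
  expect_error(shortest_path(g, "A", "Z"), "not in graph")

  # diamond with two equal-length routes: lexicographically smaller returned
  dia <- interaction_graph(data.frame(
    protein1 = c("A", "A", "B", "C"), protein2 = c("B", "C", "D", "D"),
    combined_score = rep(500, 4)))
  expect_identical(shortest_path(dia, "A", "D")$path, c("A", "B", "D"))
})

test_that("path lengths match the Floyd-Warshall oracle in both modes", {
  for (s in 1:12) {
    edges <- random_graph_edges(seed = 100 + s)
    for (mode in c("hop", "score")) {
      g <- interaction_graph(edges, weight_mode = mode)
      D <- oracle_all_pairs(g$edges, mode)
      nodes <- g$nodes
      picks <- combn(nodes, 2)[, sample(choose(length(nodes), 2), 5)]
      for (j in 1:ncol(picks)) {
        sp <- shortest_path(g, picks[1, j], picks[2, j])
        expect_equal(sp$length, unname(D[picks[1, j], picks[2, j]]),
                     tolerance = 1e-9,
                     info = paste("seed", s, mode, picks[1, j], picks[2, j]))
      }
    }
  }
})

test_that("sub-networks recover planted bridges exactly", {
  cfg <- graph_sim_config(
    n_background_nodes = 25, edge_probability = 0.15,
    seed_genes = c("TUB", "MYE", "PAR", "SLC"),
    planted_bridges = list(
      list(pair = c("TUB", "MYE"), bridge = c("ESR", "VIM")),
      list(pair = c("MYE", "PAR"), bridge = "GJA"),
      list(pair = c("PAR", "SLC"), bridge = c("GJA", "UBC"))),
    seed = 15)
  sim <- simulate_interaction_graph(cfg)
  sn <- build_subnetwork(sim$graph, cfg$seed_genes)
  expect_setequal(sn$bridge_genes, sim$bridge_nodes)  # shared node once
  # closure: every reported edge has both endpoints in the node table, and
  # every path is a connected walk in the input graph
  expect_true(all(c(sn$edges$protein1, sn$edges$protein2) %in% sn$nodes$node))
  key <- paste(sim$graph$edges$protein1, sim$graph$edges$protein2)
  for (pth in strsplit(sn$paths$path, "->", fixed = TRUE)) {
    a <- head(pth, -1); b <- tail(pth, -1)
    expect_true(all(paste(pmin(a, b), pmax(a, b)) %in% key))
  }
})

test_that("directly connected seeds need no bridges", {
  seeds <- c("A", "B", "C")
  cfg <- graph_sim_config(
    n_background_nodes = 0, edge_probability = 0, seed_genes = seeds,
    planted_bridges = lapply(list(c("A", "B"), c("A", "C"), c("B", "C")),
                             function(p) list(pair = p, bridge = character(0))))
  sim <- simulate_interaction_graph(cfg)
  sn <- build_subnetwork(sim$graph, seeds)
  expect_identical(sn$bridge_genes, character(0))
  expect_equal(nrow(sn$edges), 3)
})

test_that("missing and disconnected seeds are reported, not fatal", {
  g <- interaction_graph(data.frame(
    protein1 = c("A", "B", "X"), protein2 = c("B", "C", "Y"),
    combined_score = rep(500, 3)))
  expect_warning(sn <- build_subnetwork(g, c("A", "C", "ZZZ")),
                 "absent from graph")
  expect_true("ZZZ" %in% sn$unresolved_pairs$from |
              "ZZZ" %in% sn$unresolved_pairs$to)
  expect_identical(sn$bridge_genes, "B")
  suppressWarnings(sn2 <- build_subnetwork(g, c("A", "C", "X")))
  expect_true(any(sn2$unresolved_pairs$reason == "disconnected"))
  expect_error(suppressWarnings(build_subnetwork(g, c("A", "QQ"))),
               "fewer than 2")
  expect_error(build_subnetwork(g, "A"), "at least 2")
})

test_that("raising the score threshold never adds edges or shortens paths", {
  edges <- random_graph_edges(seed = 300, max_nodes = 15)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score",
               paste(edges$protein1, edges$protein2, edges$combined_score)), f)
  g_lo <- load_interactions(f, 0)
  g_hi <- load_interactions(f, 500)
  expect_lte(nrow(g_hi$edges), nrow(g_lo$edges))
  common <- intersect(g_lo$nodes, g_hi$nodes)
  if (length(common) >= 2) {
    prs <- combn(common, 2)
    for (j in seq_len(min(ncol(prs), 10))) {
      lo <- shortest_path(g_lo, prs[1, j], prs[2, j])$length
      hi <- shortest_path(g_hi, prs[1, j], prs[2, j])$length
      expect_gte(hi, lo - 1e-12)
    }
  }
})

test_that("all-shortest mode unions every equal-length route", {
  dia <- interaction_graph(data.frame(
    protein1 = c("A", "A", "B", "C"), protein2 = c("B", "C", "D", "D"),
    combined_score = rep(500, 4)))
  one <- build_subnetwork(dia, c("A", "D"))
  expect_setequal(one$bridge_genes, "B")
  both <- build_subnetwork(dia, c("A", "D"), all_shortest = TRUE)
  expect_setequal(both$bridge_genes, c("B", "C"))
  expect_equal(nrow(both$edges), 4)
})
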