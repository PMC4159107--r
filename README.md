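# mrmrpath

Surrogate-gene discovery for disease-phase classification: mRMR feature
selection with a correlation-based mutual-information estimator,
jackknife-validated incremental feature selection under three
nearest-neighbor-style prediction engines, and shortest-path sub-network
extraction over a scored protein-interaction graph.

## The problem

Expression studies of progressive diseases (the motivating setting is a
prostate-cancer cohort with normal tissue, primary tumor and metastatic
tumor samples) routinely report hundreds of differentially expressed
genes, but rarely a *minimal* gene set that classifies samples into
phases. `mrmrpath` implements that search end to end, for anyone who has

* an expression matrix (probes × samples) with a phase label per sample,
* optionally, a scored interaction network (STRING flat-file convention),

and wants the smallest probe set whose expression predicts the phase,
plus the interaction partners that connect the selected genes.

## The method

**Relevance and redundancy from correlation.** Mutual information between
two variables is estimated from their correlation coefficient with the
Gaussian closed form

    I(x, y) = -1/2 · ln(1 − ρ²(x, y))        (nats)

The phase label is encoded ordinally (NT = 0 < PT = 1 < MT = 2), so a
monotone expression trend along disease progression registers as
relevance.

**mRMR ranking.** Features are selected greedily. The first probe
maximizes relevance `I(x, y)`; each subsequent step adds the probe
maximizing

    q = I(x_j, y) − (1/|S|) · Σ_{x_k ∈ S} I(x_j, x_k)

i.e. relevance minus mean redundancy against the already-selected set
`S`. Greedy selection nests, so the first *N* entries of one ranking are
the mRMR solution of size *N*.

**Jackknife validation and IFS.** Each candidate subset is scored by
leave-one-out validation: every sample's phase is predicted from the
remaining samples with one of three engines — 1-nearest neighbor, a vote
of the five nearest neighbors, or the nearest class centroid — under the
cosine sample distance

    d(e₁, e₂) = 1 − (e₁ · e₂) / (‖e₁‖ ‖e₂‖)

Incremental feature selection sweeps `N = 1..max_n` over the ranking's
prefixes and picks the smallest `N` attaining the maximum accuracy
(`Accuracy = (TP + TN) / (TP + TN + FP + FN)`; overall and pairwise
phase-vs-phase accuracies are both reported).

**Network stage.** The selected genes are placed on a scored interaction
graph (edges below a combined-score threshold dropped; default 400,
STRING "medium confidence") and joined pairwise by shortest paths
(Dijkstra; unweighted hops by default, optionally score-derived weights
`1 − score/1000`). The union of the paths is the sub-network; its
non-seed nodes are the *bridging genes* — candidate co-acting factors.

**Synthetic ground truth.** Because every stage needs testable truth, the
package ships generators for (a) class-conditional Gaussian expression
with planted phase-informative probes (up/down-regulated markers whose
change onsets at different phases), noisy redundant copies, and null
background probes, and (b) scored random graphs with planted bridge
paths between declared seed genes.

## Worked example

```r
library(mrmrpath)

# a synthetic three-phase cohort (77 NT / 66 PT / 24 MT, 200 probes)
sim <- simulate_expression_dataset(expression_sim_config(seed = 1))
sim$matrix
#> Labeled expression matrix: 200 probes x 167 samples
#> Classes ( NT < PT < MT ): NT=77, PT=66, MT=24

ranking <- mrmr_rank(sim$matrix, n_features = 50)
head(ranking, 4)
#>   step   probe_id relevance mean_redundancy          q
#> 1    1 probe_0006 0.8900396      0.00000000 0.89003960
#> 2    2 probe_0007 0.8859523      0.67971143 0.20624086
#> 3    3 probe_0009 0.1686614      0.12392248 0.04473888
#> 4    4 probe_0011 0.1335777      0.09714141 0.03643626

curve <- run_ifs(sim$matrix, ranking, max_n = 50)
curve
#> IFS curve: N = 1..50, engines: vote5, nn1, centroid
#> Optimum (nn1): N = 7, accuracy = 0.988
```

The first two selections are strongly phase-correlated probes (high
relevance); the steep drop in `q` at step 2 is the redundancy penalty at
work. At this seed the optimum keeps 7 probes and classifies 98.8% of
the 167 samples correctly under leave-one-out 1-NN. Mapping the optimal
probes back to the generator's ground truth shows all four planted
marker signals captured (several through their redundant copies):

```r
truth <- sim$truth
parents <- truth$parent[match(curve$optimal_features, truth$probe_id)]
table(ifelse(is.na(parents), curve$optimal_features, parents))
#> probe_0001 probe_0002 probe_0003 probe_0004 probe_0022
#>          2          2          1          1          1
```

The network stage, on a simulated graph with planted bridge paths:

```r
gcfg <- graph_sim_config(
  n_background_nodes = 30, edge_probability = 0.1,
  seed_genes = c("TUBB6", "MYEF2", "PARM1", "SLC25A22"),
  planted_bridges = list(
    list(pair = c("TUBB6", "MYEF2"),    bridge = c("ESR1", "VIM")),
    list(pair = c("MYEF2", "PARM1"),    bridge = "NR3C2"),
    list(pair = c("PARM1", "SLC25A22"), bridge = "UBC")),
  seed = 1)
net <- simulate_interaction_graph(gcfg)
build_subnetwork(net$graph, gcfg$seed_genes)
#> Shortest-path sub-network: 8 nodes, 7 edges
#> Seed genes: TUBB6, MYEF2, PARM1, SLC25A22
#> Bridge genes: ESR1, NR3C2, UBC, VIM
```

`run_pipeline(pipeline_config(...))` chains all stages from files on
disk and writes every stage output plus a JSON run report; a thin
command-line front end with `simulate` / `rank` / `ifs` / `subnet` /
`run` subcommands lives in `inst/cli/mrmrpath`.

## Using real data

The package reads GEO-series-matrix-oriented TSVs and STRING
`protein.links`-style edge lists directly. To attempt a real run: fetch
a series matrix and a per-sample phase annotation, write them as the
expression/labels TSVs described in `?read_expression`, supply a
probe-to-gene mapping table and a STRING links file, and call
`run_pipeline()`. Probe filtering (e.g. restricting to protein-coding
genes) is the caller's responsibility; no downloading code is included.
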