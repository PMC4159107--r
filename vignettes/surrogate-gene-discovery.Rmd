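---
title: "Surrogate-gene discovery: models, choices and limitations"
author: "mrmrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-gene discovery: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmrpath)
```

This vignette is the package's own account of the statistical machinery:
what is computed, which knobs matter, what the synthetic generator does
and does not emulate, and where genuinely open design questions were
settled.

## The estimator: mutual information from correlation

Both the relevance of a probe to the phase label and the redundancy
between two probes are measured by the Gaussian mutual-information
closed form

$$I(x,y) = -\tfrac{1}{2}\,\ln\!\left(1-\rho^2_{x,y}\right),$$

the exact MI of a bivariate Gaussian with correlation $\rho$. This is a
*parametric* estimator: for non-Gaussian dependence it measures only the
linear (Pearson, the default) or monotone (Spearman, optional) part of
the association. It is fast, smooth in $\rho$, and needs no
discretization — which is why it suits a greedy scan over thousands of
probes — but it is blind to non-monotone signals by construction.

Two numerical conventions keep the greedy argmax well defined:

* $\rho^2$ is clamped at $1-10^{-12}$, so a perfectly correlated pair
  yields $I \approx 13.8$ nats instead of $\infty$. A duplicate of an
  already-selected probe therefore gets a *large finite* redundancy
  penalty, and score comparisons never involve `Inf - Inf`.
* A zero-variance feature is assigned $\rho = 0$ (hence $I = 0$) rather
  than `NA`; an undefined correlation must not poison the selection.

The categorical phase label enters as its ordinal encoding
($0,1,2,\dots$ along `class_order`). This is a modelling decision, not a
mathematical necessity: disease phases are ordered, and the ordinal
encoding lets a monotone expression trend along progression register as
relevance. A label permutation would change the results; `class_order`
is therefore an explicit, user-visible argument everywhere.

## The mRMR ranking

Selection is greedy: step 1 takes the probe with maximal relevance;
step $k$ adds the probe maximizing
$q = I(x_j, y) - \frac{1}{|S|}\sum_{x_k \in S} I(x_j, x_k)$.
Feature–feature redundancy uses the *same* correlation method as
feature–label relevance — one estimator, one scale, so relevance and
redundancy are commensurable in $q$. Ties in the argmax are broken by
input order, making the ranking fully deterministic. Because the
selected set only grows, rankings nest: `mrmr_rank(m, k)` is the first
$k$ rows of `mrmr_rank(m, n)` for $k \le n$. The IFS sweep exploits
exactly this prefix property, and a test cross-checks it against
re-running the ranker at every length.

The implementation is incremental ($O(p)$ correlations per step rather
than a $p \times p$ correlation matrix), so ranking a few hundred probes
to depth 50 takes well under a second; the greedy path is verified
against an independently coded exhaustive per-step argmax on small
random instances.

## Distance, engines, and jackknife validation

Samples are compared with the cosine distance
$d = 1 - \langle e_1, e_2\rangle / (\lVert e_1\rVert\,\lVert e_2\rVert)$,
which lies in $[0,2]$ and ignores overall expression magnitude — two
samples with proportional profiles are identical to it. Zero-norm
vectors are a hard error, not a silent `NaN`.

Three engines share this distance: `nn1` (label of the nearest
neighbor), `vote5` (majority among the five nearest; if fewer than five
reference samples exist the neighborhood truncates with a warning) and
`centroid` (nearest arithmetic class-mean). Tie rules are fixed
constants so that every prediction is reproducible: neighbor ties break
by training index, vote ties go to the tied label whose representative
is nearest, centroid ties to the earlier class in `class_order`.

Validation is leave-one-out ("jackknife"): each sample is predicted
from the other $n-1$ only. The held-out sample is excluded from the
neighbor pool *and* from centroid computation — centroids are
recomputed inside every fold — and a mutation test asserts that
changing a held-out sample's label never changes its own fold's
prediction. If leaving a sample out empties its class, that class's
centroid is omitted for the fold with a warning. Overall accuracy is
the fraction of correct multiclass predictions; pairwise phase
accuracies (e.g. NT vs MT) are computed by restricting to samples whose
true label is one of the two phases. Both are reported because neither
alone summarizes a three-class problem: the overall value is dominated
by the large classes, the pairwise values isolate each boundary.

## Incremental feature selection

`run_ifs()` scores the ranking's prefixes for $N = 1..\texttt{max\_n}$
(default `min(400, probe count)`) and `select_optimal()` applies the
"best accuracy, smallest feature number" rule. The selecting engine
defaults to `nn1` and is configurable; the choice matters only when
engines peak at different $N$, and the stored curve lets users
re-select with any engine after the fact. The sweep cost is one
jackknife evaluation per $N$ per engine; for the default synthetic
problem size (200 probes, 167 samples, $N \le 50$) a full sweep runs in
well under a second, and the problem sizes used across the test suite
were chosen so the whole suite completes in a few minutes on one core.

One behavior of the smallest-$N$ rule deserves a caveat: when a prefix
of $k$ features already attains the maximum of the accuracy curve, the
rule stops at $k$ even if later features carry genuine signal. With
three phases there are only two phase boundaries, so four planted
markers are informationally over-complete, and in roughly one cohort in
ten a three-marker prefix saturates the curve and the fourth marker is
(correctly, by the rule's own logic) left out. This is a property of
the selection rule, not a defect of the ranking — the missing marker is
almost always ranked 4th or 5th.

## The synthetic-expression generator

`simulate_expression_dataset()` draws class-conditional Gaussian
expression. Defaults mirror a three-phase cohort of 77/66/24 samples
with 4 informative probes, 2 redundant copies each and 188 null probes
(200 total — a desk-scale stand-in for a chip's ~10⁴ probes). Per
probe, the within-class standard deviation is 1, so `effect_size` is in
sd units; baselines are uniform on `baseline_range` (arbitrary
continuous units on a log-like scale; values may go negative).

Informative probes are *phase markers*: each gets a direction (up- or
down-regulated) and an onset phase, and its class mean changes by
`effect_size` per class step from the onset on, flat before. The
per-probe mean profile is monotone along the phase ordering — which is
what makes the ordinal-correlation relevance well posed — while the
*set* of markers spans non-collinear class-mean directions. The second
property is essential: if every informative probe shifted identically
(a single shared direction), the three class means would be nearly
collinear as vectors and the cosine distance, which sees only
direction, could barely separate them regardless of effect size. The
direction/onset design gives each phase boundary its own angular
signature, so at `effect_size = 5` the classes are cleanly separable by
1-NN and at `effect_size = 3` leave-one-out accuracy sits around
0.96–1.00.

Redundant probes are noisy *copies* of their parent
(`parent + N(0, redundancy_noise_sd²)`, default sd 0.1; 0 gives exact
duplicates) rather than independent redraws, so the redundancy penalty
has an unambiguous correct behavior to test: a copy must never beat an
independent informative probe to selection. Null probes are iid
Gaussian, independent of the label. The ground-truth sidecar (`truth`)
labels every probe's role, parent, direction and onset, which is what
the recovery tests and the acceptance script consume.

What the generator does *not* emulate: probe-level microarray
artifacts, normalization behavior, batch effects, heavy-tailed or
skewed expression distributions, and correlated null probes. Passing
tests on this generator therefore demonstrate that the pipeline's
machinery is correct and recovers planted structure under its stated
model — not that any particular accuracy will be attained on real
arrays.

## The synthetic-graph generator

`simulate_interaction_graph()` builds an Erdős–Rényi background among
background nodes plus planted bridge paths joining declared seed genes,
with STRING-style integer scores (background: uniform in `score_range`;
planted edges: the range maximum). Background edges are drawn only
among background nodes — never incident to seeds or bridge nodes — so
the planted paths are the only seed-to-seed routes and the planted
bridge set is an *exact* ground truth for `build_subnetwork()`. The
price is realism: the seed component is not embedded in the background
component. For testing path algorithms against an oracle the package
uses unrestricted random graphs instead.

## The network stage

Edges below `score_threshold` (default 400, the conventional
medium-confidence STRING cutoff; the threshold is explicit and
overridable) are dropped at load; duplicate pairs collapse to their
maximum score; self-loops are removed. Shortest paths default to
unweighted hops — path length then counts intermediate partners, which
matches how bridging genes are usually read — with score-derived
weights ($1 -$ score$/1000$) as an option. Distances come from igraph;
the deterministic path choice is the package's own: among equal-weight
shortest paths the lexicographically smallest node sequence is
returned, found by greedily walking admissible neighbors in identifier
order. The walk excludes already-visited nodes so it terminates even
across zero-weight edges (score 1000); on such zero-weight plateaus,
where the lexicographic optimum among non-simple walks is ill-defined,
it falls back to the library's deterministic path. `--all-shortest`
unions every equal-weight path instead, trading the single canonical
answer for completeness. Path lengths in both modes are tested against
a hand-coded Floyd–Warshall oracle on random graphs.

Missing seed genes and disconnected pairs are reported in
`unresolved_pairs` with warnings rather than aborting the analysis —
on real identifier mappings, a seed absent from the network is the
common case, not the exceptional one.

## Pipeline and reproducibility

`run_pipeline()` chains ingest → mRMR → IFS → optimum → id mapping →
sub-network, writing each stage's table plus a JSON report (config
echo, seed, versions, per-stage timings). Every analysis stage is
deterministic given the inputs; the single config seed matters only
when the inputs themselves are simulated. Re-running with identical
config and seed reproduces every output file byte for byte; the run
report is the one exception, since it records wall-clock timings.

Expression ingest is deliberately strict: probes-in-rows orientation
only (a transposed-looking file is an error, never silently fixed),
unlabeled samples are an error, labeled-but-absent samples a warning,
and probes with missing values are dropped rather than imputed —
imputation is a modelling step that should not happen silently inside
a reader.

## Known limitations

* The MI estimator sees only linear/monotone dependence; a
  non-monotone marker (up in PT, back down in MT) scores low relevance
  under the ordinal encoding.
* Jackknife accuracy at small class sizes is quantized (1/167 per
  sample here); plateaus in the IFS curve are therefore common, and
  the smallest-$N$ rule resolves them aggressively (see the IFS
  caveat above).
* Cosine distance ignores magnitude; if phases differ mainly by
  overall expression level rather than profile shape, these engines
  will underperform.
* The network stage inherits whatever identifier universe the edge
  file uses; probe-to-gene mapping quality directly bounds what the
  sub-network can show.
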