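---
title: "Flow-based reliability bounds for complex membership queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-based reliability bounds for complex membership queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A probabilistic protein interaction network assigns each interaction a
probability that it is functional. Given a partially known complex or
pathway (a set of member proteins), the membership problem asks which
other proteins in the proteome belong to it, ideally with an associated
probability. `netflow` answers this with *two-terminal network
reliability*: the probability that at least one fully operational path of
interactions connects a candidate to some member of the query set, when
every edge fails independently with one minus its weight.

Exact reliability is #P-hard (the package's `exact_reliability()`
enumerates all $2^{|E|}$ edge states and is capped at 20 edges, serving
only as an oracle). Monte Carlo estimation (`mcs_reliability()`) scales
poorly and offers no guarantee. The package's core instead computes a
*provable lower bound* from edge-disjoint paths.

## The bound

Let $d$ edge-disjoint paths join the query to a sink, path $i$ consisting
of edges with reliabilities $r_1,\dots,r_{l_i}$. The path operates only if
all its edges do, so its failure probability is
$P_i = 1 - \prod_{j} r_j$. Because the paths share no edges, their
failures are independent, giving

$$R \;\ge\; 1 - \prod_{i=1}^{d} P_i .$$

The bound is sound for *any* edge-disjoint path set and tightens as $d$
grows; by Menger's theorem the maximum $d$ equals the minimum-cardinality
edge cut between query and sink, attained by maximum flow with unit edge
capacities. When all simple query-to-sink paths happen to be pairwise
edge-disjoint the bound is exact, which the test suite exploits.

Multiple query members become a single flow problem through a virtual
super-source, connected to each member by an artificial certain edge whose
capacity equals the member's degree (so one member can head several
disjoint paths). Artificial edges never appear in reported paths and do
not count toward path lengths.

### Which maximum flow?

Maximum flows are not unique, and the bound depends on which one is
decomposed: a flow routed through long, unreliable detours yields large
$P_i$ and a useless bound even at the correct $d$. `netflow` therefore
solves a *minimum-cost* maximum flow with edge cost $-\log r$ (successive
shortest augmenting paths with Johnson potentials, in C++). Among all
maximum flows this selects the one maximizing the product of
reliabilities over flow-carrying edges. Unit paths are then peeled off the
flow most-reliable-first (shortest path on $-\log r$ restricted to flow
edges), which maximizes the resulting bound among decompositions of that
flow. Residual ties fall to a deterministic shortest-path tie-break, so
all outputs are reproducible.

This choice also matters for the search below: with an arbitrary maximum
flow we observed cluster-level bounds far *below* the true member bounds
(one 200-node fixture gave 0.0095 against a true 0.245), which breaks
pruning; with the min-cost flow the cluster bounds behave as intended.

## Why not normalize by degree?

Methods in the random-walk family divide each node's incident weights by
their sum, so evidence that routes through a hub is diluted: two
candidates behind identical 2-edge paths receive different scores if one
intermediate node has many unrelated partners. Protein networks are
scale-free, so this situation is common. Reliability-based scores use the
experimental evidence on each edge as-is; `netflow_score()` assigns both
candidates the same bound, while `random_walk_with_restart()` (provided as
a baseline, restart 0.5 by convention) ranks the hub-shadowed candidate
strictly lower. The test suite constructs exactly this contrast.

## Scaling: hierarchy, cluster graph, bandwidth

Scoring the whole proteome runs one flow instance per candidate. To prune
that work, the network is clustered hierarchically and queries descend the
hierarchy best-first.

*Nearest Neighbor Clustering* (NNC, `nnc_cluster()`) processes edges in
decreasing weight order, greedily growing/merging clusters but skipping
any action that would exceed a size bound (default 100 members, the
setting that yields ~65 clusters on a ~3100-protein network). This keeps
cluster sizes near-uniform and the maximum *inter*-cluster edge weight
low — exactly the quantity the cluster graph retains. Spectral clustering
(`spectral_cluster()`, eigenvectors of the raw similarity matrix followed
by k-means) is provided as the alternative flat scheme, but on scale-free
networks it tends to produce one huge cluster, so hierarchies
(`build_hierarchy()`) stack NNC recursively: each level reruns NNC on the
cluster graph of the level below with a larger member-count bound
(defaults 100, 400, 1600, unbounded, giving 3–4 levels at yeast scale).
Clusters that fail to merge at a level are carried upward unchanged.

The *cluster graph* replaces each active cluster by one vertex; an edge
joins two vertices iff any network edge crosses their member sets, carries
the **maximum** crossing weight, and records the crossing count
(*multiplicity*). Query proteins are removed from their home clusters and
added as individual vertices. One edge-disjoint cluster path can represent
several real disjoint paths — but no more than the multiplicity of its
first edge out of the query vertex, its *bandwidth* $b_i$ — so the
cluster-level bound is $R_{\max} \ge 1 - \prod_i P_i^{b_i}$
(`cluster_max_bound()`).

The bandwidth form alone has no admissibility proof, and it genuinely
fails when several real disjoint paths funnel through a single shared
cluster edge (e.g. two query members both reaching the target via the
same neighbouring cluster): only the first edge's multiplicity enters the
exponent, so the bound can drop below a member's true bound and prune a
true answer. `cluster_max_bound()` therefore also solves the flow problem
with every cluster edge capacitated by its multiplicity — any set of
edge-disjoint real paths contracts to a feasible flow there, and each
routed unit contributes its route's (optimistic, max-weight) failure once
— and reports the **maximum** of the two estimates. The suite still
measures empirical dominance on random hierarchies and reports any
violation count rather than hiding it. Two further safety nets: every
candidate that survives pruning is re-scored with a true whole-network
`netflow_score()` before being returned, and the degenerate
singleton-leaf hierarchy (`singleton_hierarchy()`), for which the cluster
graph is isomorphic to the network and cluster bounds equal member bounds
exactly, is kept as the reference configuration in tests.

## Threshold and budgeted queries

`threshold_query()` performs best-first search: starting from the roots,
the open cluster with the highest bound above the threshold is expanded
(ties by cluster id); leaves deliver their members as candidates; search
stops when no open cluster exceeds the threshold, pruning the rest
unexamined. Candidates are verified exhaustively and filtered at the
threshold. After each expansion only the bounds of the new children are
computed; bounds of untouched clusters are reused even though the cluster
graph changed (a `strict` flag recomputes everything for the equivalence
tests — both modes give identical answers on the tested fixtures because
of the final verification pass).

Fixed top-k lists are deliberately not a first-class mode: reliability
decays so fast down the ranking that no single k suits all queries, while
a threshold has a direct probabilistic reading. Since a good threshold is
also query-dependent, the search can adapt without losing work: cached
cluster bounds and verified scores survive a threshold change. Policies:
`halve` (halve while the answer set is empty) and `target_k` (halve until
k answers), both with a floor of $10^{-6}$.

`budgeted_query()` drops the threshold entirely: best-first expansion
orders all candidates by the bound of the leaf that delivers them, and
only the top `fraction` of the list is verified — `fraction = 0.01` spends
1% of the flow instances (a 100× speedup), `fraction = 1` reproduces the
exhaustive ranking exactly.

## Baselines

`mcs_reliability()` samples edge states and tests query–sink connectivity
per sample (breadth-first, optional path-length cutoff; 4 is the
literature default but discards genuinely connected pairs, so the default
here is no cutoff). For networks of at most 25 edges, connectivity is
evaluated once per distinct sampled edge-state pattern, which makes large
sample counts cheap on small graphs. `random_walk_with_restart()` power-
iterates $x = (1-c)\,W x + c\,e$ with column-normalized weights, uniform
restart over the query, and an L1 tolerance of $10^{-10}$.

## The synthetic testbed

No external data is downloaded; `generate_network()` emulates the summary
statistics of the yeast network the method targets:

* scale-free topology via preferential attachment; `attach_edges = 4`
  reproduces the ~4 edges/node density of the 3112-node, 12594-edge
  yeast network (the defaults);
* background weights from Beta(1, 3) — many weak edges, few strong,
  matching the observation that interacting pairs multiply rapidly as the
  probability drops;
* 27 planted, vertex-disjoint complexes of 3–15 members (the benchmark
  complement), each wired as a random spanning tree plus extra pairs to at
  least half density, with intra-complex reliabilities of at least 0.9.

`leave_one_out()` then runs the evaluation protocol: hide one member,
query with the rest, record the hidden member's rank (1-based; ties share
the best rank, and the max tie rank is also kept) and score, and aggregate
top-k recovery and per-threshold recall curves.

What the generator does **not** model: overlapping complexes, correlated
assay noise (false positive/negative structure), and the exact weight
distribution of any real network. Passing tests therefore demonstrate
algorithmic correctness and the qualitative degree-independence and
pruning behaviour, not performance figures transferable to a specific
interactome.

## Numerical and design choices

* Duplicate edge rows collapse to the **maximum** probability — the same
  max rule the cluster graph uses; probabilities of exactly 0 are rejected
  (a never-functional edge cannot contribute to any bound).
* Reliabilities live in $(0,1]$; costs $-\log r$ are finite and
  non-negative, with reduced-cost float slack clamped at zero inside the
  min-cost solver.
* k-means for spectral clustering uses 10 random restarts from distinct
  embedded rows under the caller's seed; when the requested k reaches the
  number of distinct rows the assignment is direct.
* All orderings (candidate ranking, NNC edge ties, expansion ties) break
  lexicographically so every result is deterministic.
* Test problem sizes are chosen for a desk machine: soundness and Menger
  checks enumerate graphs of at most 14 edges; pruning-optimality runs
  use 20 seeded 200-node networks with 5 planted complexes of 4–8 members,
  `attach_edges = 2` and leaf size 6. Scaling a network down compresses its
  diameter, which inflates every reliability bound; halving the attachment
  density and keeping the leaf size at the ~3%-of-nodes ratio preserves
  the low-reliability landscape that probability thresholds of 0.05–0.2
  are meant to be selective on. The budget-accounting check uses one
  ~1000-candidate network.

## Known limitations

* The cluster-level bound is a heuristic upper estimate (see above); the
  final verification pass protects the answer set, but a member of a
  pruned cluster whose true bound exceeds the threshold can be missed in
  principle. The acceptance-style tests quantify that this does not occur
  under the tested conditions.
* Exact reliability is only available for tiny instances; all large-scale
  statements rest on the lower bound and the Monte Carlo estimate.
* Edges are undirected and independent; signed, directed, or correlated
  interactions are out of scope.
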