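---
title: "Measuring hierarchy in directed networks with arborescences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hierarchy in directed networks with arborescences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbscore)
```

## The model

A *flow hierarchy* is the organizational chart idea of hierarchy: edges run
from controllers to controlled, level by level. The structure that embodies
it perfectly is the **arborescence** — a rooted directed tree with every
edge pointing away from the single root, so every node except the root has
exactly one superior and the root reaches every node by exactly one chain
of command. `arbscore` measures how hierarchical a directed graph is by how
little of it must be discarded to reach that ideal:

$$A_G = \frac{|E^*|}{|E|},$$

where $E$ is the edge set of the input (distinct ordered pairs, self-loops
included) and $E^*$ the edge set of the arborescence forest obtained by a
two-phase reduction.

**Phase 1 — condensation.** Strongly connected components are antithetical
to hierarchy: inside one, everybody reaches everybody, so there are no
levels to speak of. Each SCC is collapsed into a super-node that inherits
its members' external edges; intra-component edges (and self-loops) are
forfeited, and parallel edges between two components merge into one. The
quotient is always a simple DAG. Merging parallels is the conventional
reading of edge sets as sets; it also makes the condensed edge count
(`n_condensed_edges`, the "reduced graph" size one reports for real
networks) deterministic.

**Phase 2 — rooting.** A DAG may still have nodes with several superiors
and edges that point "up" toward a root. Both are cured at once by
enforcing in-degree ≤ 1: each multi-parent node keeps only the incoming
edge whose source has the *lowest* out-closeness

$$C_i = \frac{1}{\sum_{j \text{ reachable from } i} d(i,j)},$$

with $d$ in hops and $C_i = 0$ for nodes reaching nothing. Nodes near a
root see more of the graph over longer paths, hence have lower closeness;
keeping their edges keeps the downward flow. Closeness is computed on the
condensed DAG — phase 2 operates on phase 1's output, not the raw graph.

Whatever edges are picked, every in-degree-0 component of the condensed DAG
stays a root and every other component keeps exactly one parent, so

$$|E^*| = |V^*| - z,$$

with $z$ the number of source components. Tie-breaking (several parents
sharing the minimal closeness) therefore cannot move the score; the package
breaks ties toward the lexicographically smallest source identifier purely
so exports are reproducible. The test suite asserts this closed form on
every randomly generated graph it touches, and asserts that relabelling
nodes never changes the score, the forest's edge count, or the root count.

The score runs from 0 (the input is one SCC) to 1 (the input already is an
arborescence forest, multiple roots allowed — the reduction never deletes a
whole branch just because the graph has two roots). Self-loops can never
survive, so they strictly lower the score, consistent with reading a loop
as the smallest possible anti-hierarchical structure.

## Degenerate inputs and numerical choices

* A graph with no edges has an undefined score; `arborescence_score()`
  refuses it rather than inventing a convention.
* Isolated nodes are allowed: each becomes its own root and contributes to
  neither numerator nor denominator.
* The score is reported both as a double and as the exact fraction
  (`score_num`/`score_den`), so exact comparisons never go through
  floating point.
* SCC detection and shortest paths are delegated to igraph's C
  implementations (linear-time, iterative — no recursion-depth limits on
  deep graphs); both are cross-checked in the tests against brute-force
  transitive-closure oracles that share no code with igraph.

## Comparison measures

Three established measures are implemented as baselines, in the form used
for head-to-head comparisons:

* **Flow hierarchy**: the fraction of edges not on any directed cycle,
  computed as edges whose endpoints lie in different SCCs. FH = 1 exactly
  for DAGs, so *any* acyclic pseudo-hierarchy (e.g. a hub over a rim of
  horizontal connections with one flipped edge) gets a perfect score —
  the toy generators make this failure mode reproducible.
* **Global reaching centrality**: the mean gap between the best node's
  reach fraction and everyone else's. It is 1 only for a star; a balanced
  binary tree of height 2 scores 8/9. The unweighted (reach-fraction)
  variant is used; the path-length-weighted variant would change none of
  the qualitative contrasts the package tests.
* **Agony score** $1 - |E_a|/|E|$ given a ranking: an edge is backward when
  rank(source) ≥ rank(target). Counting *equal* ranks as backward is a
  deliberate convention — under the strict inequality the all-equal ranking
  would trivially have zero backward edges for every graph, defeating the
  measure. The convention is isolated in `agony_score_from_ranking()` so it
  can be flipped. The optimal-ranking case is implemented only for DAGs
  (topological order, score 1); minimum agony on cyclic graphs needs a
  dedicated Eulerian-subgraph solver and deliberately raises an error
  instead of risking a silently wrong answer.

## The null model

Raw scores are hard to interpret — denser graphs score lower for purely
combinatorial reasons — so significance is assessed against a null model
that keeps every node's in- and out-degree and destroys everything else.
One null replicate restarts from the observed graph and performs one
successful **double edge switch** per edge: draw edges $a \to b$ and $c \to
d$, rewire to $c \to b$ and $a \to d$, aborting (and redrawing) any
proposal that would duplicate an existing edge or create a self-loop.
Aborted proposals do not count toward the quota — "one operation per edge"
is read as one *successful* operation, which maximizes mixing. A graph
whose degree sequence admits essentially one realization (a star, say)
cannot be rewired: the standalone operation raises after 100 × n_swaps
consecutive aborts, while inside `null_test()` such a replicate keeps the
edges it has, which correctly collapses the null distribution onto the
observed score.

`null_test()` scores `n_models` independent replicates (default 1000),
each from its own seed drawn deterministically from the master seed, so
results are bit-reproducible and independent of evaluation order. The
label rule is ±2 standard deviations; at sd = 0 the rule is undefined and
the label falls back to the sign of the observed − mean gap. The pseudo
p-value is the plain fraction of nulls ≥ observed (ties count as
outscoring; no +1 smoothing). The configuration model is *not* used: it
does not preserve the exact edge count.

## Synthetic generators: what they emulate

The generators reproduce the families used to characterize the measures,
with 100-node graphs as the reference condition:

* `gen_erdos_renyi(n, m_edges)` — no hierarchy by construction; uniform
  random placement of exactly `m_edges` distinct directed edges.
* `gen_watts_strogatz_directed(n, k, p = 0.05)` — structure (clustering,
  short paths) without hierarchy. Rewiring happens on the undirected
  lattice first, then each edge gets a uniformly random direction, in that
  order.
* `gen_preferential_attachment_directed(n, m)` — hierarchy by
  construction. Growth starts from `m` isolated seed nodes, the first
  newcomer attaches to all of them, later newcomers attach to `m` distinct
  degree-proportional targets, and every edge is oriented old → new. This
  seeding makes the analytic score exact: the graph is a DAG with
  $m(n-m)$ edges, its sources are exactly the $m$ seeds, so
  $A_G = (n - m)/(m(n - m)) = 1/m$ — rooting deletes $m - 1$ of each
  newcomer's $m$ incoming edges. FH and agony are identically 1 on this
  family, which is precisely why a cycle-blind measure cannot separate it
  from its own rewirings.
* Toy topologies (`gen_star`, `gen_cycle`, `gen_wheel_flipped`,
  `gen_balanced_arborescence`, `gen_multiroot_toy`) pin the measures'
  signature behaviours: GRC = 1 only on the star; the flipped wheel is
  acyclic (FH = 1) yet half horizontal ($A_G = 0.5$); the multi-root DAG
  is perfect for FH/agony but penalized by GRC.
* `toy_dag()`, `toy_tree()`, `toy_arborescence()`, `toy_scc_graph()` are
  fixed reference graphs with scores 0.8, 0.875, 1 and 9/20 = 0.45; each
  validates its defining structural facts at construction time.

What these families do **not** emulate about real networks: degree–degree
correlations, clustering combined with cycles, weights, and scale. A green
suite shows the measures behave as designed under these controlled
conditions; it does not certify behaviour on any particular empirical
network, which is what the null-model test is for.

`sweep_scores()` records mean ± sd of each measure over seeded replicates
per edge count, and `pa_er_ratio()` forms the discrimination ratio
$H_{PA}/H_{ER}$. Grid points are target edge counts; each family realizes
them through its own parameter (ER exactly; WS via the nearest even `k`;
PA via `m = round(e/n)`, giving $m(n-m)$ edges — the closest the model can
get).

## Problem sizes and design choices in the tests

The suite checks the closed form on ~1100 random graphs (3–16 nodes, all
density regimes, with and without self-loops), SCC partitions against a
transitive-closure oracle on 460 graphs of up to 8 nodes, the $1/m$ law at
$n = 100$, $m \in \{2, 3, 5\}$ over 20 seeds each, the low-score trend for
ER/WS at 100 nodes and 500 edges over 20 replicates, the PA/ER ratio on a
three-point edge grid, and a 1000-replicate null test on a 100-node,
300-edge graph. The label-rate property (hierarchical PA graphs classify
`+`, degree-matched ER graphs do not) runs 50 trials per family at 50
nulls each and requires a ≥ 95% correct-label rate — the same rate the
full-scale protocol expects. These sizes were chosen so the whole suite
exercises every claim in minutes on one CPU while keeping each statistical
assertion comfortably away from its noise floor.

## Known limitations

* The score is strict: on dense real networks most edges die in
  condensation, and everything inside one SCC is flattened — members of a
  collapsed root are indistinguishable peers. Alternative cycle-breaking
  reductions that preserve more structure are out of scope.
* Minimum agony for cyclic graphs is not implemented (external rankings
  are accepted instead).
* Edges are unweighted and unlabelled; weighted condensation is a
  non-goal.
* `read_edgelist()` deliberately supports only the plain two-column
  format; richer formats (GraphML, GEXF) are out of scope.
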