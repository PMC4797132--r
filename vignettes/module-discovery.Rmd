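---
title: "Seed-driven network module discovery with modnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-driven network module discovery with modnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modnet)
```

modnet implements the computational core of a network-analysis workflow
for cancer cohorts: from a confidence-scored interaction source and
per-gene alteration frequencies, it extracts the subnetwork that connects
recurrently altered genes, prunes statistically unremarkable connectors,
overlays co-expression, clusters the result into modules, annotates the
modules with Gene Ontology terms, and lays everything out with modules as
geometric groups. This vignette explains the models behind each stage,
the parameters that matter, the numerical choices, and what the synthetic
test data can and cannot tell you about behavior on real cohorts.

## The data model

The substrate is an attributed, simple, undirected graph. Two constructs
extend it beyond plain graphs:

* **Groups** (compound nodes): named, pairwise-disjoint node sets with a
  display shape (`rectangle`, `circle`, `convex_hull`). Groups are how
  discovered modules become first-class objects — the layout pulls their
  members together and pushes different groups apart.
* **Hyper-edges**: relations among two or more participants with roles
  (e.g. enzyme/substrate/product). They are deliberately inert data: the
  degree, shortest-path, clustering and layout machinery all operate on
  the binary graph only, because the discovery pipeline is defined on
  pairwise interactions. Hyper-edge participants must be nodes, not
  groups — allowing groups would make group disjointness and layout
  semantics circular.

Nodes carry two mutually exclusive role flags, `seed` and `linker`, with
seed winning any conflict so that a gene that is both altered and on a
shortest path renders deterministically as a seed.

Duplicate edge input (including reciprocal A–B / B–A rows, which
interaction databases routinely contain) collapses to one undirected edge
keeping the maximum confidence score; maximum is used because it is
deterministic and monotone under re-import.

## Background sources and extraction

A *background store* persists named interaction sources as GraphML plus a
JSON manifest, so a source imported once is available by name in every
later session. Score thresholds are **strict**: `subnetwork_by_score(st,
900)` keeps edges with score > 900, the usual convention for
high-confidence STRING-style networks. Seed selection is likewise strict:
mutation frequency > 0.02 or CNA frequency > 0.03.

`extract_paths()` takes the union, over all seed pairs at unweighted
graph distance ≤ d (default 2), of **all** shortest paths between the
pair. Ties are included by construction; pairs farther apart than d
contribute nothing (d bounds the pair distance, it does not force longer
paths into the result). Non-seed nodes in the union are flagged linkers.

## The linker significance test

A linker is kept only if its connectivity to the seed set is surprising.
With N the node count of the score-filtered background (the sampling
frame actually searched — not the full unfiltered source), s the number
of seeds present in it, and a linker of background degree k with x seed
neighbors, the upper-tail hypergeometric probability

$$p \;=\; \sum_{i=x}^{\min(k,s)} \frac{\binom{s}{i}\binom{N-s}{k-i}}{\binom{N}{k}}$$

is the chance of at least x seed neighbors if the linker's k neighbors
were drawn uniformly without replacement. The test is applied once to the
initial candidate set (no iterative re-testing after removals), default
threshold p < 0.01 unadjusted, with Benjamini–Hochberg adjustment
available (`adjust = "bh"`). Both this test and the GO
over-representation below share one kernel, `stats::phyper`; the test
suite verifies both against an independent brute-force binomial summation
to 1e-10.

One property of this test worth knowing before choosing study designs:
its power collapses as the seed set grows toward the universe. If half
the background is seeds, almost any neighbor profile is unsurprising and
essentially all linkers are removed. That is correct behavior of the
statistic, not a defect, but it means seed-dense designs yield seed-only
subnetworks (see the limitations section).

Pearson correlation of expression profiles then becomes the edge weight:
signed r is stored for display (`weight`), |r| separately as the
clustering affinity (`similarity`), since flow-based clustering needs
non-negative affinities. Zero-variance genes get weight 0 with a warning
(r undefined); genes absent from the matrix leave weight 1 and are
flagged.

## Clustering: MCL and MCODE

**MCL** simulates flow: the similarity-weighted adjacency matrix gains
self-loops (each node's maximum incident weight — this prevents the
classic period-2 oscillation on bipartite-ish structures), is
column-normalized, and is then alternately *expanded* (matrix power,
default 2) and *inflated* (entrywise power, default 2.0, then column
renormalization) with entries below `pruning_threshold` (1e-5) zeroed,
until the maximum column change falls below 1e-8 or `max_iter` (100) is
reached. Non-convergence returns the current interpretation with a
`converged = FALSE` flag and a warning, never an error. Clusters are read
off the attractor structure: nodes with positive limit flow on the
diagonal are attractors, attractors connected in the limit matrix form
attractor systems, and every node joins the system holding most of its
column flow — ties broken toward the lexicographically smallest attractor
id so results are independent of input order. Cluster lists are ordered
by size descending, ties by smallest member id; size-1 clusters are
reported as `singletons`.

The inflation exponent controls granularity, and its effect is strong:
on planted-partition graphs with 5 modules of 20 nodes, within-module
edge probability 0.3 and between probability 0.02, inflation 2.0
over-fragments (mean adjusted Rand index against the planted labels
≈ 0.55 over 20 seeds, with clusters of 3–7 nodes), while inflation 1.6
recovers the planted modules well (mean ARI ≈ 0.94). We verified the
fragmentation at inflation 2.0 against an independent reference
implementation of MCL, which produces the identical partition — it is a
property of the algorithm at that granularity setting on graphs of this
density, not of this implementation. The package default stays at the
conventional 2.0; for module recovery on sparse networks we recommend,
and the test suite characterizes, inflation around 1.6.

**MCODE** scores each vertex by the structure of its closed neighborhood:
the highest k-core of the neighborhood is found, and the vertex weight is
that core's k times its edge density. Vertices below `degree_cutoff` (2)
are never seeds and carry weight 0 (so edgeless graphs yield no
complexes). Complexes grow breadth-first from the highest-weight unvisited
seed, admitting neighbors whose weight is at least
`(1 - vertex_weight_percentage)` × seed weight (default slack 0.2);
grown nodes are marked visited, so complexes are disjoint. The optional
*haircut* (default on) iteratively removes members bound to the complex
by a single edge; *fluff* (default off) adds boundary neighbors whose
neighborhood density exceeds 0.5. All ties break lexicographically by
node id, making the output provably independent of input node order (the
suite permutes inputs to check this). Complex scores are density × size,
the original MCODE ranking.

`clusters_to_groups()` promotes the top-k largest non-singleton clusters
to groups labeled `cluster_1..k`; overlapping clusters refuse promotion
because groups must stay disjoint.

## GO over-representation

The ontology loader reads OBO `[Term]` stanzas, keeps `is_a` edges only
(the smallest defensible propagation closure — `part_of` and other
relationships are ignored and documented as such), drops obsolete terms,
and rejects cyclic `is_a` graphs. Annotations (GAF 2.x or 2-column
`gene<TAB>term` TSV; GAF rows with NOT qualifiers are skipped, evidence
codes filterable) propagate to all ancestors per the true-path rule.

The test universe defaults to every gene with at least one propagated
annotation — standard over-representation practice, rather than all
network nodes, because unannotated genes carry no information for the
test — and is overridable. Query genes outside the universe are dropped
with a warning and the query size reduced accordingly, which avoids
silently deflated p-values. Terms annotating fewer than `min_term_size`
(3) universe genes are skipped. Adjustment defaults to Benjamini–Hochberg
across the tested terms; the multiple-testing procedure and the universe
are exposed as arguments precisely because published descriptions of such
utilities frequently leave both unstated.

## Layout

The layout is a damped spring-electrical system. Per iteration, each
node feels:

* spring forces along edges, `spring_constant` × (distance −
  `rest_length`), defaults 0.1 and 50 units;
* inverse-square repulsion from every other node,
  `repulsion_constant` / d² (default 5000), multiplied by
  `group_repulsion_gain` (2.0) when the two nodes belong to different
  groups;
* for grouped nodes, an attraction toward their group centroid scaled by
  `group_attraction_gain` (3.0) times the spring constant;
* a weak *gravity* toward the origin, stiffness 0.02 per unit distance.

Velocities are damped by 0.9 each step and integrated with step size 0.3;
the run stops when mean per-node displacement falls below
`convergence_tol` (1e-3 units) or at `max_iter` (500). Initial positions
come from a seeded uniform disc, so a (network, parameters, seed) triple
reproduces its coordinate trace bitwise. Coordinates are re-centered on
the origin every iteration — the forces are translation-invariant, so
this changes nothing dynamically, and doing it inside the iteration (not
once at the end) is what makes a run split into `step_layout()` chunks
bitwise-identical to the unsplit run. That equivalence is also the
dynamic-reconfiguration contract: `step_layout()` uses the parameters
passed *now*, so changing, say, `group_attraction_gain` mid-run takes
effect immediately, which the suite verifies by measuring group
contraction over the following iterations.

Two of these choices deserve justification. *Gravity* is not part of the
textbook spring-electrical model, but without it any disconnected network
(two modules with no cross edges, a common outcome of strict filtering)
has no equilibrium — components repel forever and the convergence
tolerance is never reached. A weak origin spring bounds the system while
leaving relative geometry dominated by the other forces. *Step size and
gravity defaults* (0.3, 0.02) were fixed together by a stability scan:
on the two-clique reference fixture the system converges in ≈ 170
iterations with an inter-centroid distance about 6× the mean intra-group
radius, and a pure two-node spring settles at the rest length to within
0.01%. Exact pairwise repulsion is used rather than a Barnes–Hut
approximation to keep determinism trivial; the cost is quadratic per
iteration, which is irrelevant at the network sizes this pipeline
produces (tens to hundreds of nodes).

Group outlines are computed from final coordinates: bounding box,
smallest centroid-centered covering circle, or convex hull, each padded
outward (default `rest_length`/5); singleton groups degenerate to a
padded point rather than erroring. `layout_frames()` snapshots the state
every k iterations for animation; the last frame equals the
`run_layout()` result by construction.

## Data-to-visual mapping

`visual_mapping()` declares a monotone map from a data attribute to a
visual channel: numeric ranges for node size / edge width, 2–3 anchor
color gradients for node/edge color. Interpolation is linear in RGB
(hex sRGB in all exports — chosen for bit-exact testability over
perceptual spaces); a diverging gradient requires an explicit 3-value
domain so the midpoint anchor is never guessed. Out-of-domain values
clamp to the nearest endpoint or are flagged hidden; missing values get a
neutral grey / range midpoint plus an `absent` flag; a constant attribute
under an `"auto"` domain maps everything to the range midpoint with a
warning rather than dividing by zero.

`overlay_series()` renders one styled frame per experimental condition on
*identical* coordinates, with a single domain shared across conditions by
default — the point of a serial overlay is comparability, so the gene
holding the series-wide maximum gets the range-maximum style whichever
condition it occurs in. Per-condition domains are a flag away.

## The synthetic cohort generator

`planted_network()` draws a planted-partition graph: within-module edge
probability `p_in`, between-module `p_out`, confidence scores uniform on
a configurable range. `simulate_omics()` adds a one-factor-per-module
expression model — gene g in module m is
`sqrt(rho)·f_m + sqrt(1-rho)·noise`, giving any within-module gene pair
population correlation exactly `rho`, which is what makes the generator
verifiable: the suite checks the realized mean within-module correlation
against `rho` to ±0.05 at 200 samples — plus per-condition mean shifts
and an alteration table in which a chosen fraction of each altered
module's genes draws mutation/CNA frequencies above the selection
thresholds and every other gene draws below them.

The packaged reference fixture (`gbm_like_fixture()`) uses 5 modules × 20
genes, p_in 0.3, p_out 0.02, scores uniform on (850, 1000) so the
score > 900 filter genuinely bisects the edge set, 60 samples, rho 0.6,
half of every module's genes altered, and three conditions with a +1 mean
shift rotating over modules. These values were chosen once as a plausible
desk-scale emulation of a tumor-cohort analysis and are deliberately not
tuned to any downstream outcome.

What the generator does **not** emulate: scale (real backgrounds have
10⁴–10⁷ edges), degree heterogeneity (hubs), mutational signatures or
CNA segment structure, expression heavy tails and batch effects, or
annotation bias. Passing tests on these fixtures demonstrate algorithmic
correctness and determinism, not performance on real cohorts.

## Known limitations

* **MCL granularity at the default inflation.** As measured above,
  inflation 2.0 fragments sparse planted modules (mean ARI ≈ 0.55);
  recovery requires ≈ 1.6 on graphs of that density. The default follows
  convention; users clustering sparse filtered subnetworks should lower
  it.
* **Seed-dense designs defeat the linker test.** In the reference
  fixture, half of all genes are seeds; no linker reaches p < 0.01, the
  extracted network is seed-only and sparse, and end-to-end module
  recovery at all-default parameters lands around ARI 0.4–0.5 —
  substantially below what the same clustering achieves on the unfiltered
  planted graph at moderate inflation. Both effects are faithful
  consequences of the statistics at these study conditions; the
  acceptance script reports the measured values rather than idealized
  ones.
* **Layout convergence is seed- and size-dependent**; larger networks may
  hit `max_iter` still moving (the state says so via `converged`), and
  coordinates are abstract units for consumers to scale.
* The OBO reader covers the `[Term]`/`is_a`/`is_obsolete` subset relevant
  here, not the full OBO 1.4 grammar; GAF parsing keeps symbol-level gene
  ids with no identifier mapping layer (inputs are expected pre-resolved,
  as interaction files are).

## Problem sizes in the test suite

The suite exercises: 1 000 randomized hypergeometric cases (N ≤ 30)
against an exact summation oracle; 20 planted-partition seeds at 100
nodes for clustering recovery; layout fixtures of 10 nodes with 100–500
iterations; and full pipeline runs on the 100-gene reference cohort,
twice, to assert byte-identical artifacts. The complete suite runs in
well under a minute on one CPU.
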