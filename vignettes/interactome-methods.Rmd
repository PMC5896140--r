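---
title: "Methods: topology, controllers and robustness of directed interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology, controllers and robustness of directed interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermnet)
```

## The problem

A cell's interactome — its molecules as nodes, their interactions as
directed links — is not wired democratically. A small minority of nodes
(hubs, bottlenecks) carries most of the connectivity and most of the
information flow, and this topology has concrete biological consequences:
a network whose control is concentrated in ~2–3% of its nodes is almost
immune to random component failure, because random damage almost never
lands on a controller. This package implements the full analysis chain
for such networks as it is practiced on curated pathway data: assembly
from pathway exports, topological characterization, controller
identification, robustness simulation, and an essentiality check of
controllers against knockout phenotypes. Spermatozoa are the motivating
system — transcriptionally and translationally silent cells whose
behaviour is governed almost purely by the architecture of their
inherited protein network — but every function is generic over directed
networks with string node identifiers.

## Network model and assembly

The core container is a directed network over non-empty string node IDs:
an edge record is `(source, interaction, target, score)` with an optional
integer confidence score in 0–1000. Edge sets have set semantics:
duplicate `(source, interaction, target)` triples collapse, keeping the
**maximum** score (the best evidence for an interaction certifies it).
Self-loops are legal; they count once toward in- and once toward
out-degree but are excluded from neighborhoods and never lie on shortest
paths.

Assembly mirrors how curated interactomes are actually built:

1. **Union-merge** of pathway edge-list files (SIF or TSV).
2. **Harmonization**: synonym identifiers are renamed to canonical ones
   via an alias table. Resolution is deliberately one-step — a table
   containing chains (`a → b`, `b → c`) is rejected up front rather than
   resolved transitively, because a chained alias table almost always
   indicates a corrupted mapping. Harmonization is idempotent and can
   only shrink the node set.
3. **Enrichment**: candidate interactions (e.g. association-database
   exports) are admitted only when their confidence score is *strictly*
   greater than the threshold (default 900 of 1000, i.e. score ≥ 901),
   and only between nodes already present in the harmonized union.
   Enrichment completes the network among its own molecules; it never
   expands the node set. Records without a score cannot certify their
   confidence and are dropped with a warning. Association sources that
   carry no direction can be added in both directions
   (`enrichment_mode = "undirected"`); the default adds rows as listed.

## Topology panel

`topology_report()` computes the standard parameter panel. Two views of
the graph coexist deliberately:

* **Path metrics are directed.** Diameter (longest finite shortest
  path), characteristic path length (mean shortest-path length over
  reachable ordered pairs), the count of reachable ordered pairs and its
  percentage of $N(N-1)$, and betweenness centrality (normalized by
  $(N-1)(N-2)$) all follow edge direction.
* **Neighborhoods are undirected.** The local clustering coefficient is
  the classical $C_I = 2n_I / k_I(k_I-1)$, where $n_I$ counts links
  among the $k_I$ distinct neighbors of node $I$ (direction ignored,
  self excluded, $C_I = 0$ when $k_I < 2$), because that formula is
  defined on the undirected neighborhood. "Average number of neighbours"
  is likewise the mean count of distinct adjacent nodes.

Weak connectivity defines components: a merged pathway union is never
strongly connected, and the main component — on which all downstream
analysis runs by default — is the largest weak component. Its share of
the network is reported as a percentage rounded to one decimal.

Graph plumbing (components, BFS distances, betweenness, triangle counts)
is delegated to igraph; the package's tests verify every path-based
quantity against a brute-force Floyd–Warshall oracle with explicit
path-count accumulation on hundreds of random digraphs.

### Degree distributions and power-law fits

A scale-free network has $P(k) \sim k^{-\gamma}$. The reporting
convention, matching the network-analyzer tools used on curated
interactomes, is ordinary least squares on
$(\log_{10} k, \log_{10} \mathrm{count})$ over occupied bins
($k \ge 1$, count $\ge 1$; zero bins have no logarithm and are omitted;
no log-binning). The fit reports the signed slope $\gamma$, the Pearson
correlation $r$ of the logged pairs, and $R^2 = r^2$. A flat histogram
is degenerate ($\gamma = 0$, $r$ reported as 0, flagged).

This estimator is known to underestimate the exponent magnitude: the
deep tail of any finite degree histogram is a noisy band of count-1
bins that drags the slope toward shallower values. On
preferential-attachment networks of 5000 nodes the OLS magnitude sits
near 1.9 even though the generative exponent is 3. For that reason the
package also provides `fit_power_law_mle()`, the discrete
maximum-likelihood estimator
$\hat\gamma = 1 + n / \sum_i \ln(k_i / (k_{\min} - \tfrac12))$ with the
tail cutoff $k_{\min}$ selected by minimizing the Kolmogorov–Smirnov
distance between the empirical and fitted tails. The MLE recovers
exponents in the classical 2–3 band on generated networks and is the
right tool for *estimating* an exponent; the OLS fit remains the
default because it is the convention whose $r$ and $R^2$ appear in
published topology tables. `clustering_vs_degree()` applies the same
log–log estimator to mean clustering per degree class: hierarchical
networks show $C(k) \sim k^{-1}$, preferential-attachment networks a
flat, low-$R^2$ relation.

## Controllers

**Hubs** are nodes whose total degree is at least one standard
deviation above the network mean, $k \ge \mu + \sigma$. The standard
deviation is the *population* value — the network is a census of
itself, not a sample. Both the degree flavor and the multiplier are
configurable. In the degenerate all-equal-degrees case $\sigma = 0$ and
every node qualifies; this is reported with a warning rather than
hidden.

**Hub subpopulations.** The density of a hub metric (typically the
clustering coefficient) is estimated with a Gaussian kernel, Silverman
bandwidth $h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$,
evaluated on a 512-point grid spanning $[\min - 3h, \max + 3h]$.
Subpopulation boundaries are the valleys of this density, with two
numerical guards. First, density below $10^{-8}$ of the maximum is
clamped to zero and a zero-run flanked by positive density counts as a
single valley at its midpoint — the FFT-based density evaluation
otherwise fabricates dozens of "minima" from floating-point wiggle in
empty regions. Second, a valley must sit at least 20% below the smaller
of its two flanking peaks (`min_valley_drop = 0.2`) to count: every
finite-sample KDE carries shallow ripples, and a mode claim should
require a substantial valley. Setting the drop to 0 restores the raw
strict-minimum rule. The biological reading follows the party/date hub
distinction: party hubs engage their partners simultaneously (low
clustering), date hubs at different times or places (high clustering).

**Bottlenecks.** For every root $s$, a breadth-first shortest-path tree
$T_s$ is grown over directed edges; among equal-distance predecessors
the lexicographically smallest identifier becomes the parent, making
the tree — and therefore every score — deterministic. A non-root node
$v$ earns the indicator $p_s(v) = 1$ when more than $|V(T_s)|/4$ of the
root's paths meet at $v$, where "paths meeting at $v$" is the size of
$v$'s subtree ($v$ plus descendants: every path to a descendant passes
$v$, and the path ending at $v$ itself is counted). The bottleneck
score is $BN(v) = \sum_s p_s(v)$. Roots are excluded in their own tree,
otherwise every root would inflate every score by one. The published
formula leaves both "meet" and the tree choice unspecified; these
conventions are declared here and shared by the exhaustive path-walking
oracle the tests compare against, so the equivalence check is exact.

**Control backbone.** Each controller set (all hubs; the top-$k$
bottlenecks, $k$ defaulting to the hub count so the two sets are
comparable) induces a neighborhood network — the controllers, their
first neighbors (direction ignored for membership), and all induced
edges. The backbone is the intersection of the hub and bottleneck
neighborhood networks: the region of the interactome governed by both
kinds of controller.

## Robustness

`attack()` measures degradation of the relative main-component size
$S(f)$ as a fraction $f$ of nodes is removed. Random failure removes a
fresh seeded permutation per replicate; targeted attack removes nodes
in descending total-degree order computed **once** on the intact
network — the static convention of the foundational attack-tolerance
experiments (adaptive recomputation is available by flag). Removal is
cumulative within a replicate, so $S(f)$ is non-increasing by
construction rather than by assertion. On scale-free networks the two
curves separate immediately: random failure rarely hits a hub, targeted
removal dismembers the giant component. The companion number is
`hub_hit_probability()`, the percentage of nodes that are controllers —
the chance a uniformly random failure matters at all.

## Knockout-phenotype association

Controller essentiality is tested against knockout-mouse fertility
annotations. Nodes carry one of four phenotype categories (infertile;
hypofertile; fertility affected; fertility unaffected/normal);
unannotated nodes are the "not studied" mass and are excluded before
tabulation, never treated as a fifth category. The 4×2
phenotype-by-class table (hub / non-hub) is tested with the
**uncorrected** Pearson chi-square statistic
$\sum (O-E)^2/E$, $df = (r-1)(c-1)$. No Yates correction: the
correction is a 2×2 device, this table has $df = 3$, and only the
uncorrected statistic is comparable with published values for this
design. Column percentages are rounded half-up to one decimal (the
spreadsheet convention used in printed tables; base R's `round()`
rounds half to even). A minimum expected count below 5 triggers a
warning, since the reference table itself has thin hub cells.

## Synthetic data: what it emulates and what it does not

Every input the pipeline needs can be generated, so all stages are
testable without database access.

* `generate_ba()` grows a directed preferential-attachment network:
  a complete symmetric clique on $m_0$ nodes (avoiding zero-degree
  attachment pathologies), then one node per step drawing $m$ distinct
  targets with probability $k_i / \sum_j k_j$ on **total** degree
  (matching the hub definition downstream), edges directed new→target,
  duplicate draws rejected and redrawn. Defaults $N = 2000$, $m = 2$
  give a mean total degree near 4 — the scale and sparsity of a
  mid-sized curated interactome (which run in the thousands of nodes
  with mean degree ≈ 3.7).
* `fragment_network()` produces what a pathway-database export looks
  like: 32 overlapping pathway edge-list files covering every edge, a
  synonym table applied inconsistently across fragments (each aliased
  node appears as its synonym in a random half of the fragments — the
  realistic annoyance harmonization exists to fix), and a scored
  enrichment table with a configurable share above the 900 threshold.
  Its central guarantee, tested over many seeds: `assemble()` on the
  output reconstructs the source network bit-exactly whenever the
  above-threshold enrichment share is zero.
* `simulate_phenotypes()` samples which nodes are studied (35.6% of
  hubs, 19.6% of non-hubs by default — hubs are better studied) and
  assigns categories from per-class multinomials whose defaults are the
  reference knockout-table proportions (hubs .238/.143/.143/.476;
  non-hubs .278/.174/.275/.272). Printed one-decimal percentages sum to
  0.999, so probability vectors within 0.005 of 1 are accepted and
  renormalized.
* `planted_hub_metrics()` draws the party/date clustering-coefficient
  mixture — uniform on $[0, 0.17]$ and $[0.83, 0.89]$ — used to
  exercise subpopulation recovery.

What the generators do **not** emulate: correlated evidence between
pathways, species-mapping noise, degree-dependent annotation bias
within a class, directionality errors, or the hierarchical clustering
structure of real pathway unions (the BA model has flat $C(k)$, real
interactomes often do not). A passing suite therefore certifies the
algorithms and their conventions, not the biological conclusions one
would draw from any particular real network.

## Determinism and problem sizes

Every stochastic function takes an integer seed and is bit-reproducible
given it; the pipeline derives stage seeds from one master seed and
echoes them in its report. Ties are always broken lexicographically
(BFS parents, component ordering, hub and bottleneck rankings), so no
result depends on node insertion order.

The test and verification sizes are chosen so exhaustive oracles stay
exact: path metrics and betweenness against Floyd–Warshall with
path-count accumulation on digraphs up to 30 nodes (500 cases),
bottleneck scores against full tree enumeration up to 8 nodes
(500 cases), exponent recovery on 5000-node generated networks across
10 seeds, attack asymmetry on 2000-node networks with 20 replicates
over removal fractions 0.01–0.30, and assembly round trips and
subpopulation recovery across 20 seeded configurations each.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(seed = 11L), out_dir = "spermnet-out")
report$controllers$hub_criterion$hub_pct   # share of nodes that are hubs
report$phenotype$chi_square$p_value        # simulated KO association test
```

## Known limitations

* Betweenness and distance computations materialize chunked distance
  blocks; networks beyond ~10^5 nodes would need a sparser strategy.
* The bottleneck census builds one BFS tree per root in R; it is exact
  and deterministic but quadratic, sized for networks of up to a few
  thousand nodes.
* The OLS exponent is reported for comparability, not accuracy; use the
  MLE when the exponent itself is the question.
* The chi-square test is asymptotic; with thin cells (expected < 5) the
  warning should be taken seriously and an exact test considered
  externally.
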