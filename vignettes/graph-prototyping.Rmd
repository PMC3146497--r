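---
title: "Graph prototyping: selecting representative networks from a cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph prototyping: selecting representative networks from a cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Integrative network analysis often starts from a set of networks that all
describe the same biological question — for example co-expression networks
inferred from several independent expression studies of the same disease,
one network per study and patient group. Deriving common conclusions from
such a set usually means matching edges across networks, which is brittle
when vertex namespaces differ and expensive when they do not. Graph
prototyping sidesteps edge matching: it selects one member of the set, the
*graph prototype*, as the representative of the whole set, and then performs
topological analysis on that single network.

Given a set $\mathcal{G} = \{G_1, \dots, G_m\}$ of undirected simple graphs
with unique vertex labels and a graph distance measure $d$, the prototype is

$$ G^* = \arg\min_{G_i \in \mathcal{G}} \; \bar d_i, \qquad
   \bar d_i = \frac{1}{m-1} \sum_{j \ne i} d(G_i, G_j). $$

The criterion always selects exactly one network (ties broken by input
order and reported), regardless of how large the distances are; it is a
selection rule, not a quality judgement, and deliberately applies no upper
threshold on $\bar d$. It is also not a consensus construction: no new
graph is synthesized.

```{r}
library(graphproto)
co <- make_cohort(n_vertices = 200, seed = 42)
dm <- distance_matrix(co$graphs, "pged")
select_prototype(dm[1:6, 1:6])   # prototype of the first group
```

## The five distance measures

One measure compares graphs edge by edge; four compare probability
distributions of structural features and therefore do not require a shared
namespace in general (here they are applied to cohorts that do share one).

**Normalized graph edit distance (`pged`).** For uniquely-labeled graphs on
a common vertex set, no vertex operations are needed and, with unit cost
for edge insertion and deletion, the minimum edit cost is exactly
$|E_1 \,\triangle\, E_2|$, the size of the edge-set symmetric difference —
the NP-complete general edit distance collapses to a linear-time count. We
report it normalized by the maximum possible edge count:
$\mathrm{pGED} = |E_1 \triangle E_2| / \binom{n}{2}$, so the maximal edit
(complete vs edgeless) scores 1 and sparse biological networks score far
below 1. The normalization constant is a `max_edges` argument for users who
prefer a different reference.

**Kullback-Leibler divergences (`kld_*`).** For a structural distribution
$P$ of graph $G_1$ and $Q$ of $G_2$,
$D(P \| Q) = \sum_i P_i \log (P_i / Q_i)$, computed after zero-padding both
vectors onto their union support and substituting a small $\varepsilon$
(default $10^{-10}$) for every zero entry of either vector. Four
distributions are used:

* *degree* — $P(k)$, fraction of vertices with $k$ neighbours, $k \ge 0$;
  computed on the complete, possibly disconnected network, so aligned
  isolates occupy the $k = 0$ bin;
* *distance* — $P(\ell)$, fraction of finite unordered vertex pairs at
  shortest-path distance $\ell$, $\ell = 1..\rho(G)$ with $\rho$ the
  diameter; infinite distances in disconnected graphs are simply not
  counted;
* *spheres* — a distribution over vertices: each vertex gets an
  information-functional value $f(v) = \sum_{j \ge 1} c_j\,|S_j(v)|$,
  where $S_j(v)$ is the $j$-sphere (vertices at exact distance $j$ from
  $v$) and the weights $c_j = b^j$ decay geometrically (default $b = 0.5$),
  emphasizing the neighbourhood information spreads into first;
  $p(v) = f(v) / \sum_u f(u)$;
* *orbits* — $P(s)$, fraction of automorphism-group vertex orbits of size
  $s$: how much topological vertex equivalence the network carries.

The sphere and orbit measures are defined on connected graphs, so
`graph_distance()` reduces each input to its largest connected component
(deterministic tie-break by smallest member label) before computing them;
the other three see the full graph.

## Conventions and numerical choices

Several conventions are genuinely open choices; the package fixes defaults,
exposes each one as an argument, and records the values in force in every
output table header.

* **KLD direction.** $D$ is asymmetric. Pairwise matrices store
  $d_{ij} = D(P_i \| P_j)$, and mean distances default to the *outgoing*
  (row) direction, $\bar d_i = \mathrm{mean}_j D(P_i \| P_j)$; incoming
  means are available via `direction = "in"`. Prototype selections can
  differ between the two; the choice is therefore logged prominently.
* **$\varepsilon$-substitution.** Zeros are replaced, not renormalized: the
  total perturbation is at most (support size)$\cdot\varepsilon$, far below
  every quantity of interest, and substitution keeps $D$ finite when the
  reference has mass on a bin the other graph misses. $\varepsilon$ must
  stay well below $1/n$; the default $10^{-10}$ satisfies this for any
  realistic cohort.
* **Support alignment.** Distributions of the same kind are zero-padded to
  the union support (degree from $k = 0$, distance and orbit from 1; sphere
  distributions align on the union of vertex label sets). Truncation to the
  common support would discard exactly the bins where graphs differ.
* **Logarithm base.** Natural log (nats) by default, base 2 available.
  Prototype selection only compares divergences, so the choice never
  changes a selection.
* **Orbit computation.** Vertex orbits are obtained exactly from generators
  of the automorphism group (the BLISS canonical-labeling backend of
  igraph) closed under union-find. Plain 1-dimensional color refinement is
  not sufficient — it can merge non-equivalent vertices — and the test
  suite checks the orbits against brute-force enumeration of all vertex
  permutations on an exhaustive corpus of small connected graphs.
* **Tie-breaking.** Prototype ties within $10^{-12}$ are reported and
  broken by input order; component-size ties by smallest vertex label. All
  runs are deterministic given inputs and configuration.

## Between-group statistics

With two named groups (say benign and cancer), the within-group distance
samples are compared per measure by a two-sided Wilcoxon rank-sum test,
exact when both samples have at most 25 tie-free values and the normal
approximation with continuity correction otherwise, with Bonferroni
correction by the number of measures tested. For the symmetric pGED each
unordered pair contributes one value; for the directed divergences both
orderings are kept. Feature clustering follows the same pattern used for
heatmap displays: each measure's within-group mean distances are min-max
normalized over all graphs jointly — without the group information — and
the graphs are clustered agglomeratively with Euclidean distance under
complete (default) or average linkage.

A caveat that matters when interpreting these p-values: the
$m_g(m_g - 1)$ within-group distances of a group of $m_g$ graphs are *not*
independent — every graph participates in $2(m_g - 1)$ pairs — while the
rank-sum null assumes independent samples. The effective sample size is
closer to $m_g$ than to $m_g^2$, and simulation under an exchangeable null
(both groups rewired from one base graph at equal noise, the package's own
acceptance experiment) shows the realized false-positive rate of the
Bonferroni-adjusted test well above its nominal level. The test is
implemented as the field uses it, but its p-values should be read as
descriptive ranking evidence, not calibrated error rates; a graph-level
permutation test would be the calibrated alternative and is left as future
work.

## Prototype topology

`topology_summary()` characterizes a selected prototype: the 15 largest
distinct degree values with the number of vertices attaining each (hub
table, full graph), and — on the largest connected component — per-vertex
eccentricities, the diameter (maximum eccentricity), the average
shortest-path length, and the mean local clustering coefficient, with the
convention that vertices of degree < 2 contribute 0 rather than being
excluded. Two prototypes' eccentricity distributions are compared with a
two-sample Kolmogorov-Smirnov test; eccentricities are small integers, so
ties are expected and the approximate p-value is reported.

## The synthetic cohort generator

Real inputs to this method are inferred co-expression networks: sparse,
with heavy-tailed degree distributions, on a gene namespace shared across
studies after identifier mapping. `make_cohort()` emulates exactly these
features and nothing more. A base graph is grown by preferential
attachment (each new vertex attaches `attachment_edges` edges to existing
vertices with probability proportional to degree + 1, giving exactly
$m(n - m)$ edges and a scale-free tail); each cohort member is an
independent rewiring of the base in which a fixed fraction of edges is
removed and replaced by uniformly sampled non-edges, preserving the edge
count so that distances reflect rewiring rather than density.

Defaults: 500 vertices, `attachment_edges = 2` (sparse, tree-plus-shortcuts
density comparable to thresholded association networks), group sizes 6 and
7 as in the prostate-study cohorts this design mirrors, rewiring fraction
0.05 per group — enough noise that cohort members are clearly distinct
(about 5% of edges moved) while the groups remain internally coherent —
and a shared base graph, which is the exchangeable null configuration.
The generator is deliberately *not* a model of expression data: it
produces no expression matrices, no inference noise, no hub-specific
biology. Passing tests on these cohorts demonstrates that the measures,
selection rule and statistics behave as specified on graphs with the right
sparsity and tail structure; it does not validate network inference, and
measured effect sizes on real cohorts may differ.

Two properties of the generator interact with the degree divergence in a
way worth knowing. The scale-free tail holds its hubs in bins of count 0
or 1, so as soon as a hub degree differs between two graphs the
$\varepsilon$-substituted term $P_i \log(P_i/\varepsilon)$ is paid in
full; the divergence therefore rises quickly at small rewiring fractions
and then saturates, which compresses the contrast between moderately and
strongly rewired groups. Together with the dependence caveat above this
limits the power of the degree-divergence Wilcoxon comparison at the
default noise level; the acceptance experiment quantifies both effects.

## Problem sizes used in the test suite

The automated tests run on cohorts of 500-vertex graphs for planting and
group-separation experiments (50–200 replicates), an exhaustive
isomorphism-class corpus of connected graphs with up to 6 vertices plus
100 random 7-vertex graphs for the orbit oracle, and random graphs of up
to 30 vertices for the shortest-path oracle — sizes at which the
independent brute-force oracles are exact and fast while the generated
graphs still show the sparse scale-free structure of interest.

## Known limitations

* The Wilcoxon p-values inherit the dependence problem described above.
* Sphere and orbit measures silently summarize only the largest connected
  component; on cohorts whose components are comparable in size this
  discards structure.
* The sphere functional's geometric weights are one reasonable choice
  among many; other decaying weight schemes change $p(v)$ and can change
  selections.
* `pged` requires the aligned common namespace; it is not defined across
  graphs with genuinely different vertex sets.
* Automorphism-orbit computation is exact but its cost grows with graph
  symmetry; near-asymmetric biological networks are the cheap case.
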