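---
title: "Netdis with ego-network sub-sampling: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Netdis with ego-network sub-sampling: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

`egonetdis` compares undirected simple networks through the topology of
their local neighbourhoods. For every node $p$ of a network $G$ we extract
the **two-step ego-network**: the induced subgraph on all nodes within two
edges of $p$, including all edges among those nodes. In each ego-network we
count the connected induced subgraphs on $k$ nodes, for every isomorphism
class $w \in A(k)$; $A(3)$ has 2 classes (path, triangle) and $A(4)$ has 6
(path, claw, cycle, paw, diamond, complete). The default is $k = 4$, which
is the usual compromise between topological resolution and cost; $k = 3$ is
supported throughout.

Raw counts are dominated by ego size and density, so they are **centered**:
from each ego's count $N_w$ we subtract the expected count $E_w$ among
ego-networks of similar edge density in a **reference** network. The
reference's egos are binned by density (bin width 0.01 by default) and
$E_w$ is the mean count of type $w$ in the ego's bin; a query density whose
bin is empty in the reference falls back to the nearest non-empty bin, with
ties resolved towards the lower density. Summing the centered counts over
(all or sampled) ego-networks gives one vector per network,
$S_w(G)$.

Two networks are compared through the rescaled sums
$s_w(\cdot) = S_w(\cdot) / \sqrt{S_w(G)^2 + S_w(H)^2}$ and the normalised
inner product

$$\mathrm{netD2s}(G, H) =
  \frac{\sum_w s_w(G)\, s_w(H)}
       {\sqrt{\sum_w s_w(G)^2 \; \sum_w s_w(H)^2}} \in [-1, 1],$$

bounded by the Cauchy–Schwarz inequality, and the distance

$$\mathrm{Netdis}(G, H) = \tfrac{1}{2}\,(1 - \mathrm{netD2s}) \in [0, 1].$$

Types with $S_w(G)^2 + S_w(H)^2 = 0$ carry no information about the pair
and are excluded from all three sums rather than producing 0/0; if every
type is excluded the comparison is reported as degenerate (an `NA` entry in
a distance matrix) instead of a spurious 0.

## Sub-sampling ego-networks

The expensive step is the per-ego census, which is linear in the number of
nodes. Because $S_w$ is a sum over egos, it can be estimated from a uniform
random subset of ego-networks: `sample_spec()` supports a sampling fraction
(rounded up, so every positive fraction draws at least one ego) or an
absolute count. The package also implements the seed-plus-neighbourhood
bootstrap that motivates the scheme theoretically: seeds are drawn
uniformly with replacement, each seed brings in its whole two-step
neighbourhood (the "dependency neighbourhood": two nodes are dependent
precisely when each lies in the other's two-step ego-network), and the
result is summarised as an empirical measure with masses proportional to
inclusion counts, normalised to total mass 1
(`bootstrap_sample()`).

The theory behind the bootstrap says the approximation is good when the
dependency neighbourhoods are of comparable size and do not overlap too
much on average. `neighbourhood_stats()` computes proxies for those
conditions: the exact neighbourhood sizes $\gamma_i$ (two-step
neighbourhood minus the node itself), their coefficient of variation, an
estimated mean pairwise Jaccard overlap, the number of nodes with
$\gamma_i$ outside $[\bar\gamma/\tau, \tau\bar\gamma]$ (default
$\tau = 3$), and the number of large dense ego-networks. These are
heuristic proxies, not the constants of the formal bound, which involve
quantities that are not computable from the statistics we retain.

`flag_subsampling_risk()` turns the proxies into an advisory report. The
flag fires on (a) highly dispersed neighbourhood sizes, (b) heavy overlap
among *unequal* neighbourhoods — a fully uniform structure such as a single
clique has complete overlap but exchangeable nodes, and sampling any one
ego already determines all of them, so uniform structures are exempt — or
(c) a *minority* of large dense (clique-like) ego-networks, the canonical
failure case: a small region radically unlike the rest of the network is
easily missed (or over-represented) by a small uniform sample. A sparse
random graph with roughly 10,000 nodes and 15,000 edges plus a disjoint
30-clique triggers (c): the clique egos have 30 nodes at density 1 while
the background egos average about 10 nodes at tree-like densities. The
report never blocks computation.

## Random-graph benchmarks

`benchmark_suite()` reproduces the synthetic study design: five replicate
networks from each of six models — Erdős–Rényi $G(n,m)$, the erased
configuration model, 3D geometric random graphs on the unit cube,
geometric graphs grown by point duplication, the Chung–Lu expected-degree
model, and duplication-divergence growth — with parameters matched so each
model's mean degree is approximately a common target (20 by default,
matching the large-network designs; large-network variants conventionally
drop Chung–Lu, which converges to the configuration model). The
ground-truth clustering labels each network by its generating model.

Where the models have conventions rather than canonical definitions we fix
literature-standard rules and treat them as this package's definitions:

* **configuration**: stub matching on the prescribed degree sequence with
  subsequent erasure of self-loops and multi-edges; the degree sequence is
  taken from the first duplication-divergence network of the same suite,
  so the two models share degrees but not finer structure.
* **geometric duplication**: 5 seed points uniform in the unit cube; each
  subsequent point duplicates a uniformly chosen existing point plus an
  isotropic Gaussian offset ($\sigma = 0.05$ by default) clipped to the
  cube; points within the connection radius are linked.
* **duplication-divergence**: growth from a single edge; each new node
  picks a uniform anchor, copies each anchor edge independently with
  retention probability $p$, and links to the anchor with probability
  $q = 0.5$; $p$ is the free parameter used for degree matching.
* **Chung–Lu**: independent edges with probability
  $\min(1, w_i w_j / \sum_k w_k)$; the weights default to the companion
  duplication-divergence degree sequence, rescaled during matching.

Degree matching uses the closed form $m = nd/2$ for Erdős–Rényi and
bisection on the free parameter elsewhere, scoring each candidate by the
mean degree of 5 generated graphs and stopping within 5% of the target.
Isolated nodes are kept so $n$ is exact.

The generators emulate the benchmark conditions — cluster structure by
model family at matched size and density — not empirical protein
interaction data: degree sequences, clustering spectra and component
structure of real PPI networks are richer than any of the six models, so a
perfect score here shows the statistic separates model families, not that
it resolves any particular biological question.

## Evaluation

Classification quality of a distance matrix against ground-truth clusters
is measured by two nearest-neighbour scores: **1-NN**, the fraction of
networks whose nearest other network is in the same cluster, and
**k_C-NN**, where each network in a cluster of size $C_G$ is scored by the
fraction of its $C_G - 1$ nearest others in its own cluster, averaged over
networks. Ties in distance are broken towards the lexicographically
smallest name, which makes the scores deterministic and auditable; random
tie-breaking was rejected for reproducibility. Singleton clusters have
$k = 0$ and are skipped. Chance level is estimated by scoring random
symmetric Uniform(0,1) distance matrices (50 by default); its expectation
for 1-NN has the closed form $\frac{1}{n}\sum_G (C_G - 1)/(n - 1)$, which
the test suite verifies by Monte Carlo.

## Numerical and design choices

* **Census algorithm.** Per-ego counts are computed in compiled code from
  degree, per-edge codegree and wedge statistics, followed by the exact
  linear conversion from subgraph-copy counts to induced counts. The test
  suite proves equality with an independent exhaustive-enumeration oracle
  across densities. Counts accumulate in doubles, exact below $2^{53}$.
* **Expectation table.** $E_w$ is the per-bin *mean raw count*. A variant
  that rescales expectations by ego size within a bin exists in the
  literature; with density-matched references of similar ego scale the two
  readings are close, and the mean-count reading keeps the self-centering
  identity exact: a table built from $G$ itself yields $S_w(G) = 0$ for
  every $w$ (a property the tests assert).
* **Reference.** Any user-supplied edge list can serve as the reference;
  the built-in default is an Erdős–Rényi graph with 5,000 nodes and 50,000
  edges, which keeps the tool usable with zero downloads and is the
  standard sensitivity-analysis reference for this statistic.
* **Determinism.** Every stochastic step derives from one run seed through
  fixed substreams keyed by purpose and graph name (so adding a graph to a
  run does not perturb the other graphs' samples), and per-graph ego
  samples are drawn once per run and reused across all pairwise
  comparisons, keeping the distance matrix internally consistent.
* **Degenerate inputs.** Self-loops in edge lists are dropped (the census
  is defined on simple graphs) and counted in a warning; edge weights are
  ignored with a warning; egos with fewer than 2 nodes have density 0 and
  land in the lowest bin; egos with fewer than $k$ nodes contribute
  $0 - E_w$ to the centered sums, like any other ego.
* **Ego census scope.** All induced $k$-subsets of an ego-network are
  counted, whether or not they contain the ego; restricting to subgraphs
  through the ego is a coherent alternative we did not implement.

## Problem sizes used by the tests

The packaged experiment (`run_experiment()`) runs a five-model suite
(Erdős–Rényi, configuration, geometric, geometric duplication,
duplication-divergence) of 5 replicates at $n = 1000$ and mean degree
$\approx 20$, centred on the built-in Erdős–Rényi reference, sweeping
sampling fractions with 20 repetitions each — a deliberately desk-scale
version of the published designs at $n$ up to $10^5$ with 250 repetitions.
At this scale the full-sampling 1-NN score exceeds the random baseline
several-fold and a 10% ego sample stays close to the full-sample score;
exact values are computed, not asserted, by the test suite.

## Known limitations

* Only undirected, unweighted simple graphs; $k \in \{3, 4\}$.
* The expectation table conditions on ego density alone; references whose
  ego sizes differ grossly from the query network's shift all centered
  sums systematically. That shift cancels between networks of similar
  scale but is visible when comparing networks of very different sizes
  against one reference.
* Networks whose centered sums are dominated by noise (e.g. replicates of
  the reference model itself at the reference's own scale) produce noisy
  pairwise distances; this is a property of the statistic, not of the
  sampling.
* The balance diagnostics are proxies; they can miss pathologies that the
  formal bound would catch, and the advisory thresholds are heuristics.
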