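---
title: "Detecting protein complexes with distance-restricted clique merging"
author: "cpdr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes with distance-restricted clique merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdr)
```

## The problem

Protein complexes appear in protein–protein interaction (PPI) networks as
dense, compact subgraphs, and a single protein often belongs to several
complexes at once, so the detection problem is one of *overlapping*
community detection. The classic clique percolation method (CPM) finds
k-clique communities — unions of k-cliques chained through shared
(k−1)-vertex overlaps — but in PPI networks it behaves badly at the
extremes: small k percolates a large fraction of the network into one
giant, biologically meaningless community, while large k leaves mostly
isolated cliques. Curated complexes, by contrast, are meso-scale objects
(roughly 5–25 proteins) and topologically compact: for the large majority,
every pair of members lies within two hops of each other.

`cpdr` implements a detection algorithm that exploits that compactness
directly, together with the CPM baseline and the standard evaluation
battery for complex prediction.

## The model

The input is an undirected simple graph $G(V, E)$: self-interactions and
duplicate pairs are removed on construction (`build_graph()`), and protein
identifiers are opaque, case-sensitive strings.

Every maximal clique of size at least `min_clique_size` (default 3) is
initialised as a *basic cluster unit*. Two units $U$ and $V$ merge when
both hold:

1. **Shared-vertex condition.** $|U \cap V| \ge N$ with
   $N = \min(|U|, |V|) - 1$. The threshold adapts to the smaller unit: for
   two triangles it reduces to the edge-sharing adjacency of CPM at
   $k = 3$, but two large cliques must be almost identical before they
   merge. This is what prevents the giant-component percolation that CPM
   suffers at small $k$.
2. **Distance restriction.** The subgraph induced by $U \cup V$ is
   connected with diameter at most $d$ (default $d = 2$). Only edges with
   both endpoints inside the union count — paths may not detour through
   outside vertices. A disconnected union has infinite diameter and can
   never merge, which makes the condition total.

The scan works over a pool of units in a fixed canonical order (size
descending, then lexicographic on the sorted member list). Each unit $U$
is compared against every other pool unit; every pair that satisfies both
conditions appends the union $U \cup V$ at the tail of the pool (one union
per partner — this pairwise-union rule is how overlapping clusters arise),
and $U$ is deleted after its comparisons if it merged at least once.
Passes over the pool repeat until one completes without any merge. The
fixpoint iteration makes the result insensitive to the encounter order
within a pass, which a single pass would not be.

Two corner rules matter in practice:

* a union identical to $U$ itself (its partner is a subset of $U$) is not
  counted as a merge for $U$ — otherwise the superset would be deleted and
  its members lost; the subset is absorbed when its own turn comes;
* exact duplicate member sets are collapsed, but clusters that are proper
  subsets of other clusters are *kept* by default (`absorb_subsets =
  FALSE`), since distinct merge histories may legitimately end in nested
  vertex sets.

Every emitted cluster is a union of maximal cliques, has at least 3
members, and has induced diameter at most $d$ — the last two are asserted
as invariants in the test suite.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 2 | maximum induced diameter of a cluster, in hops. 2 reflects the observed compactness of curated yeast complexes; raising it admits more elongated clusters and approaches plain percolation behaviour. |
| `min_clique_size` | 3 | smallest maximal clique used as a basic unit. 3 is the smallest size with non-trivial internal structure; raising it discards sparse regions entirely. |
| `threshold` (evaluation) | 0.2 | overlap-score cutoff at which a predicted cluster and a known complex count as matched. |

## Evaluation battery

Against a gold-standard catalog (complexes with at least two members;
singletons are discarded on load) the package computes:

* **Overlap score** $OS(P_c, K_c) = i^2 / (|P_c| \cdot |K_c|)$ with $i$
  the number of shared proteins; 1 for identical sets, 0 for disjoint
  ones. The shared-*protein* reading of $i$ is used; gold-standard
  complexes are plain protein sets carrying no edge information, so a
  shared-edge reading would be uncomputable.
* **Sensitivity** $TP/(TP+FN)$, **specificity** $TP/(TP+FP)$, and their
  harmonic mean **f-measure** $2 \cdot Sn \cdot Sp/(Sn+Sp)$. The harmonic
  mean form is verified in the test suite to reproduce, to nine decimals,
  all four published f-measure values from the study this algorithm
  family comes from — an exact arithmetic identity, so it pins the
  definition. Because match counting is two-directional (several
  predictions can match one complex and vice versa), both the matched
  prediction count and the matched known-complex count are reported, and
  the sensitivity denominator is overridable (`known_denominator`).
* **Overlapping rate**: mean number of clusters each covered protein
  belongs to, $\sum_i N_i / |\{v : k_v \ge 1\}|$, plus the fraction of
  covered proteins in more than one cluster.
* **Hypergeometric enrichment**: upper-tail probability (including the
  observed count) that a cluster of size $C$ contains at least $k$ of the
  $F$ proteins in a functional category, in a network of $N$ proteins;
  each cluster is assigned the category minimising the P-value, ties
  broken lexicographically. Dotted category codes are treated as flat,
  independent labels — no hierarchy propagation, since annotation schemes
  differ in how they would propagate.
* **Complex–complex overlap network**: all cluster pairs sharing at least
  one protein.

## The synthetic benchmark generator

`generate_benchmark()` plants `n_complexes` vertex sets in a chain where
consecutive complexes share `overlap_size` vertices; within a complex each
pair is an edge with probability `intra_density`, and `noise_edges` random
edges are added between pairs not inside any planted complex. The chain
topology (rather than random overlap pairs) makes the expected behaviour
of the merge rule on each adjacent pair analytically derivable. Defaults —
10 complexes, sizes uniform on 5–25, overlap 2, density 1, 50 noise
edges — emulate a meso-scale complex landscape over a small background.

What the generator does *not* emulate: scale-free background topology,
degree-correlated noise, false-negative interaction dropout at realistic
rates, or complexes that are themselves sparse. Passing the planted-
recovery tests therefore demonstrates algorithmic correctness under
controlled conditions, not expected accuracy on experimental interactome
data.

Two derivable consequences used in the tests: at density 1 every planted
complex is a clique (induced diameter 1, comfortably inside $d = 2$); and
with overlap 2, two planted cliques of size ≥ 4 satisfy CPM's $k = 3$
adjacency but *fail* the shared-vertex condition ($N = \min - 1 \ge 3$), so
percolation chains them while distance-restricted merging keeps them
apart — the two algorithms are deliberately compared on such corpora.

## Numerical and implementation choices

* **Determinism.** All set orderings use radix (byte-wise) sorting, so
  output files are byte-reproducible across locales; the generator takes
  an explicit seed and restores the caller's RNG state.
* **Merge engine.** The scan is implemented twice: a literal, list-based R
  reference, and a compiled engine (bitset membership, popcount overlap
  tests, bounded BFS for the diameter check, verdicts memoized per union)
  used by `cpdr_clusters()`. The two are asserted identical — members and
  provenance — on random graph corpora in the test suite. The compiled
  engine exists because the pairwise-union rule can create large numbers
  of transient intermediate units around big cliques with many small
  attachments before everything collapses to the fixpoint; one benchmark
  instance in the test corpus creates ~5000 intermediates on a 96-vertex
  graph.
* **Degenerate inputs.** Empty graphs yield empty cluster lists (not
  errors); graphs with no clique of the minimum size likewise. A
  single-vertex member set has induced diameter 0. `network_stats()`
  computes diameter and mean path over the largest connected component
  (interaction networks are usually disconnected) and scores degree-0/1
  vertices as 0 in the clustering-coefficient mean.
* **Clustering coefficient convention.** Degree < 2 vertices contribute 0
  rather than being excluded; one convention had to be fixed and this is
  the common graph-library default.
* **Vertices seen only in self-interactions** are dropped: they would be
  isolated and can participate in no clique, no community and no cluster.

## Problem sizes used in the checks

The test suite validates enumeration and percolation against brute-force
oracles on random graphs of up to 12 vertices (exhaustive subset
enumeration is exact there), the hypergeometric tail against explicit
combinatorial sums for all configurations with $N \le 25$, and the full
pipeline on 100 planted benchmarks (10 complexes of size 5–25 each).
These sizes keep the whole battery exhaustive where exhaustiveness is
feasible and statistical where it is not.

## Known limitations

* The pairwise-union scan can be expensive on graphs whose noise
  structure attaches many small cliques to one large clique; runtime is
  governed by the number of distinct intermediate unions, not by graph
  size per se.
* Cluster counts on real interactome snapshots depend on the scan order;
  the canonical order used here is fixed and documented, but other
  implementations of the same algorithm family may order differently and
  emit slightly different (equally valid) cluster inventories.
* Enrichment treats annotation codes as flat labels; users wanting
  hierarchy-aware enrichment should propagate annotations before loading.
* No multiple-testing correction is applied to enrichment P-values; they
  are screening scores, not calibrated significance statements.
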