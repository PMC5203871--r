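---
title: "Typed network construction, hub selection and functional enrichment for multi-herb formulas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed network construction, hub selection and functional enrichment for multi-herb formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis this package implements

A multi-herb formula is not a single-target drug: each herb contributes
several active compounds, each compound binds many proteins, and the
therapeutic effect — if any — emerges from how that set of proteins sits
inside the human interactome relative to the disease's known therapeutic
targets. `netpharm` implements the standard network-pharmacology workflow
for this situation as a typed-graph pipeline:

1. **Typed network construction.** Four views are built from relation
   tables: (1) herb → compound → pharmacological action → traditional
   effect; (2) the compound–target bipartite network; (3) a formula-level
   view in which compounds are contracted out and each herb links directly
   to the union of its compounds' predicted targets, with disease targets
   attached through their protein–protein interactions; (4) the PPI
   network induced over the predicted targets, the disease targets and
   every protein interacting with at least one of them. Node roles
   (`compound_target`, `infertility_target`, `shared_target`,
   `other_protein`, ...) are a partition: a protein both predicted for a
   compound and listed for the disease is a `shared_target`.
2. **Three-index hub selection.** Every node of the PPI view is scored by
   degree, pair-normalized shortest-path betweenness and component-scaled
   closeness. A node is a *main node* when all three indices are at or
   above the network-wide mean of that index. The induced subgraph on the
   main nodes, with nodes lacking any direct interaction removed, is the
   direct-interaction hub network.
3. **Over-representation analysis.** Gene lists (the target set; the main
   nodes) are tested against a gene-set collection with the upper-tail
   hypergeometric probability and fold enrichment
   $\mathrm{FE} = (k/n)/(K/N)$, where $k$ of the $n$ list genes and $K$ of
   the $N$ background genes carry the term. Benjamini–Hochberg q-values
   are reported alongside; significance filtering mirrors common practice
   by cutting on the raw p (default $p < 0.05$) with q informational.
   Significant terms are collapsed greedily (a term is absorbed by a more
   significant term when the Jaccard overlap of their list-restricted
   member sets exceeds 0.5) and the top non-redundant terms become
   functional modules; each gene joins the covering module with the
   smallest p.

Because the upstream services that produce the real inputs (pharmacophore
mapping, therapeutic-target and interaction databases, annotation servers)
are web resources, the package ships seeded generators that emulate the
statistical structure of their exports, so every stage is testable
offline and end-to-end runs are reproducible down to file bytes.

## Definitions and numerical choices

**Degree** is the incident-edge count on the simple, undirected graph.

**Betweenness** is Brandes shortest-path betweenness with fractional
credit over equally short paths, endpoints excluded, divided by
$(N-1)(N-2)/2$. Normalization matters here: the above-mean rule compares
nodes against a network-wide average, and on a ~1500-node interactome the
meaningful thresholds (order $10^{-3}$ and below) only arise on the
normalized scale. Graphs with fewer than three nodes have no interior
pairs and are defined to have zero betweenness.

**Closeness** uses the Wasserman–Faust component-scaled form: for node
$v$ in a component of size $n_v$ inside a graph of $N$ nodes,

$$ C(v) = \frac{n_v - 1}{N - 1}\cdot\frac{n_v - 1}{\sum_{u} d(v, u)} , $$

with the sum over $v$'s component and $C(v) = 0$ for isolated nodes. On a
connected graph this is the familiar $(N-1)/\sum d$; on a disconnected
graph it avoids the infinite distances while still penalizing small
components, which is the behaviour of the network-analysis tools this
workflow is normally run in. The ends of a path A–B–C therefore score
$2/3$ and the middle scores $1$; each node of two disjoint triangles
scores $2/5$.

**Main-node rule.** Thresholds are the arithmetic means of each index over
*all* nodes, isolates included, and the comparison is inclusive
($\geq$). Inclusivity is deliberate: on a vertex-transitive graph every
node ties the mean and the rule selects all of them rather than none. The
selection is monotone — raising a node's three indices never removes it.

**Score filter.** Interaction tables carry a combined confidence score in
$[0,1]$ and are filtered *strictly* above the threshold (default 0.4):
an edge scoring exactly 0.4 is excluded. Duplicate orientations of a pair
collapse keeping the maximum score; self-interactions are dropped and
counted. When independent interaction sources are merged, the merge is a
set union after canonicalization, with curated sources that carry no
combined score assigned 1.0.

**Enrichment.** The test is the plain hypergeometric upper tail
($p = P(X \geq k)$); an `ease = TRUE` switch computes the conservative
variant with one success discounted, for comparability with annotation
servers that use it, but it is off by default since nothing in the
workflow depends on it. The background universe is the genes of the
annotation collection intersected with the analyzed network's gene space,
which keeps the analysis self-contained. Result ordering breaks p-value
ties by descending fold enrichment and then term id, so output is total
and stable.

**Determinism.** Every writer sorts its output canonically (edges by
endpoint pair, GMT terms and members lexicographically, node tables by
descending degree then id, reals fixed to six decimals), so identical
inputs produce byte-identical artifacts and the pipeline manifest's md5
hashes are stable across runs and platforms.

## What the generators emulate — and what they do not

`generator_config()` collects the study-scale defaults: 6 herbs, 11
mapped compounds, 233 predicted targets of which 4 are promiscuous (hit
by all compounds), 9 disease targets of which 2 overlap the predicted
set, and 1259 other interacting proteins.

- **Compound–target table.** Pharmacophore-mapping exports show a strong
  center/periphery pattern: a few targets are predicted for every
  compound, most for one or two. The generator plants the promiscuous
  targets exactly and draws the remaining per-target compound counts from
  a truncated geometric law on $[1, n_\text{compounds}]$
  (`target_skew_q = 0.855`, mean ≈ 4.5 at default scale — chosen so the
  expected pair count at study scale, ≈ 1075, matches the scale of a real
  export). Any right-skewed law satisfying the promiscuity constraint
  would do; the geometric is the simplest to parameterize.
- **Interaction table.** A preferential-attachment graph (heavy-tailed
  degree distribution, fully attached, anchors placed in the early
  well-connected core) with i.i.d. uniform$(0.15, 1)$ confidence scores,
  making the strict 0.4 filter's expected loss analytic:
  $25/85 \approx 29.4\%$. The edge count of the attachment rule is exactly
  $m(m-1)/2 + (n-m)m$ with $m = \text{round}(d/2)$, which the tests use
  as a closed-form expectation.
- **Planted hubs.** With `n_hubs > 0` the generator overlays hubs wired
  to `hub_attach_frac` of all nodes on a sparse background and records
  them as ground truth. The default regime (fraction 0.6 over a
  mean-degree-2 background) was chosen, by simulating candidate regimes
  at design time, as the weakest overlay at which the planted hubs
  unambiguously dominate all three indices; under weaker overlays
  background nodes legitimately pass the above-mean gates and "recovery"
  stops being well defined rather than the selector being wrong.
- **Annotations.** One planted term whose overlap with a designated gene
  list realizes a requested fold enrichment within 10% (the overlap size
  is the rounded solution of $\mathrm{FE} = kN/(nK)$, with an error when
  the request exceeds the attainable maximum $\min(n,K)\,N/(nK)$), plus
  uniformly sampled background terms. The default sizes (universe 800,
  list 40, term size 40, 50 terms) make rank-1 recovery of a fold-4
  planted term near-certain by a Poisson bound on the background terms'
  tail, so the recovery suite measures the statistic, not luck.
- **Study-scale bundle.** `generate_study_bundle()` writes the six input
  files at the full cardinalities and then post-processes the interaction
  scores so three structural facts hold with certainty rather than with
  high probability: every other protein keeps at least one
  above-threshold interaction with a seed; every disease-only target but
  one keeps an above-threshold interaction with the target universe; and
  exactly one disease target has none, so it appears in the PPI view
  (seeds are always retained) but not in the herb–target–disease view
  (where a disease target enters only through an actual interaction).
  This reproduces the characteristic census drift of such analyses, where
  the formula-level view shows one fewer disease target than the PPI
  view.

The generators do *not* emulate: evidence-channel structure or score
correlations of real interaction databases (scores are independent of
topology), pharmacophore match scores, annotation-term dependency (the
GO graph), or biased symbol vocabularies. Passing tests therefore
demonstrate that the pipeline's graph operations, selection rule and
statistics are correct under the stated structural assumptions — not that
any particular biological conclusion holds on real exports.

## Degenerate inputs and tie-breaks

Empty pharmacology tables yield herb–compound networks; an empty or
fully-filtered interaction table leaves the PPI view with seed nodes
only (all-zero indices make every node a main node, and the
direct-interaction subnetwork is then empty); a disease set wholly
contained in the target set yields no `infertility_target` role. Degree
ties in node tables break by node id; p-value ties in enrichment break by
fold then term id; duplicate interaction rows keep the maximum score.
Module partitioning with fewer non-redundant significant terms than
requested returns what exists and says so.

## Problem sizes used by the test suite

The suite exercises exact small cases against independent oracles
(adjacency-power path counting and Floyd–Warshall for the centralities on
all random graphs with up to 8 nodes over 200 seeds; explicit binomial
sums for every hypergeometric configuration with $N \leq 25$), recovery
properties at moderate scale (100 seeds for planted-term rank-1 at fold
4, 50 seeds for hub recovery, 20 seeds for the filter-loss rate with
~3000 edges per graph), and the full study-scale bundle (1499 nodes,
~78k scored interactions) for the census identities and the end-to-end
manifest determinism. These sizes keep a full run of the suite under a
couple of minutes while leaving every statistical check comfortably
powered.

## Known limitations

- The black-edge rule of the formula-level view (which interactions tie
  disease targets into the target set) and the contraction of compounds
  into herb–target edges are modelling choices; real studies vary here
  and the package implements one defensible reading (union of compound
  targets; filtered PPI restricted to the target universe).
- The direct-interaction hub network is produced by isolate removal after
  induction. An alternative reading — restricting main nodes to members
  of enriched terms before induction — is available by passing any gene
  set as the `main` argument of `main_node_subnetwork()`.
- Fold-enrichment values depend on the chosen background; with a
  different universe convention (e.g. a whole-genome background) the
  absolute numbers shift even though the ranking is stable.
- Betweenness and closeness are unweighted; confidence scores act only
  through the filter, never as edge weights.
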