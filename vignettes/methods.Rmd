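---
title: "Methods: deriving mutually exclusive miRNA signature modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving mutually exclusive miRNA signature modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsignet)
```

## Overview

`mirsignet` derives, for each of a collection of neoplasm groups, modules of
miRNAs that (a) are densely interconnected by functional similarity of their
target genes and (b) occur — as a connected set — in that neoplasm group
only. The pipeline has five stages: association harmonization, consensus
target mapping, GO-based miRNA–miRNA similarity, per-group network
construction with top-decile pruning, and exclusive-module selection with a
permutation null. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
worlds used in testing do and do not demonstrate.

## Association harmonization

Association tables from different databases use different column layouts
and inconsistent miRNA and disease spellings. Dialects are declared as
small column-mapping configurations (`association_dialects()`) rather than
hard-coded parsers, because the exports differ only in column naming.
miRNA names are canonicalized to miRBase style: species prefix enforced,
the mature token re-cased from `mir` to `miR`, arm suffixes (`-5p`/`-3p`)
and precursor indices preserved verbatim. Precursor siblings such as
`hsa-miR-199a-1-5p` and `hsa-miR-199a-2-5p` remain distinct: they are
distinct miRBase entries even though their mature sequences coincide.

Disease terms are rolled up to broader neoplasm groups strictly through a
supplied curated mapping; lookups are case- and punctuation-insensitive but
otherwise exact, and a term that maps to more than one group is treated as
ambiguous and dropped with a warning. The closed-world rule (unmapped terms
return a sentinel and are removed, never guessed) keeps the mapping
declarative and auditable. Deduplication collapses records to unique
(miRNA, group) pairs with the contributing source databases merged into a
sorted list, so the same association reported by two databases carries two
provenance entries but counts once.

## Consensus targets

A gene counts as a target of a miRNA when at least `min_tools` distinct
prediction tools report the pair; the default of 4 out of a 5-tool panel
reads the "more than three tools" consensus rule literally as >= 4. Votes
count distinct tools, never rows, so duplicated rows in one tool's export
cannot inflate support. The threshold is uniform: no category of
prediction bypasses the vote. Raising `min_tools` is monotone (it can only
shrink target sets), and setting it to the panel size yields the
intersection across tools — both properties are tested.

## GO-based similarity

**Information content.** Annotations are propagated to all ancestors (the
true-path rule) before counting. A term's annotation probability is the
fraction of annotated genes in its namespace carrying it after propagation,
and IC(t) = −ln p(t). Only ratios of ICs enter the Lin measure, so the
logarithm base is a documentation choice, not a numerical one. The
namespace root always has IC 0 and is therefore uninformative.

**Term similarity.** The default measure is Lin,
`2·IC(MICA)/(IC(t1)+IC(t2))`, with the most-informative common ancestor
taken over the reflexive ancestor closure; it is bounded in [0, 1], which
matches the 0.6 edge threshold scale. Normalized Resnik
(`IC(MICA)/max IC in the namespace`) is available as an alternative.
Cross-namespace pairs have no common ancestor and score 0 with a warning.
The graph-topology-hybrid family of term measures is deliberately out of
scope.

**Aggregation.** Set-to-set comparisons use the best-match average: the
mean of row maxima plus the mean of column maxima, halved. Gene-gene
similarity is the BMA over the two genes' propagated *informative*
(IC > 0) term sets, computed per namespace and averaged over the
namespaces in which both genes are informative; excluding IC-0 terms keeps
the identity `sim(g, g) = 1` exact, which a root term in the matrix would
otherwise destroy. miRNA–miRNA symmetric similarity is the BMA over the
gene-similarity matrix of the two target sets.

**Asymmetric measure.** The second edge source realizes two stated ideas —
ancestor-and-descendant-aware term affinity, and statistical weighting of
terms — as a declared approximation (`mirgofs_like_similarity`), clearly
isolated so a faithful port of the published measure could replace it.
Term affinity is the Jaccard index of the two terms' combined up+down
closures; the directed score S(A→B) averages each A-side term's best
affinity in B's term set, weighted by the term's hypergeometric
significance in A's targets; the reported value symmetrizes the two
directions. Significance weights are `min(1, −log10 p / cap)` with
`cap = log10(|universe|)`: the cap anchors full weight at the smallest
p-value a universe of that size can produce, so one vanishing p-value
cannot dominate the average. When every weight is zero (all terms
uninformative), the directed score falls back to the unweighted mean.

**Edge construction.** The 0.6 cutoff is applied per source and the
surviving pairs are unioned, matching the order of operations in the
workflow this package realizes (score, select per source, combine, drop
duplicates). An edge records whichever source weights passed; the combined
weight used for pruning is their maximum, on the rationale that a
union-style merge admits an edge on either source's strength. Similarity
is only computed among miRNAs associated with at least one neoplasm group.

## Networks and pruning

One undirected weighted graph per group: nodes are the group's miRNAs,
edges the globally computed similarity edges restricted to those nodes
(edges are computed once, so a pair carries the same weight in every
network containing both members). Pruning keeps the top weight decile by
the nearest-rank convention: the cutoff is the value at rank
`ceiling(0.9·E)` of the ascending weights and only *strictly greater*
weights survive. This convention is chosen because it reproduces the
reference arithmetic exactly — 2,415 distinct weights leave 241 —
where interpolated percentiles would leave 242. Ties at the cutoff are all
dropped (strictness applies to the value, not the rank), which makes the
rule deterministic and independent of sort order. Nodes isolated by
pruning are removed, which is what shrinks a 70-node graph to 39 nodes in
the reference example; edge removal alone cannot drop nodes. Pruning on
the combined weight is the default; the weight column is a parameter.

Topology reports include the mean local clustering coefficient
(`2·triangles/(deg·(deg−1))`, 0 for degree < 2), the degree dispersion
index (variance/mean: 1 under a Poisson law, 0 for regular graphs, far
above 1 for hub-dominated graphs), and a chi-square goodness-of-fit
p-value against Poisson(mean degree) with adjacent bins pooled until every
expected count reaches 5 (reports with fewer than three pooled bins are
untestable and carry NA).

## Module selection and the permutation null

Candidate modules are maximal cliques of size >= 3 in each pruned network —
the deterministic reading of "dense subgraphs not contained in any larger
one". A lone miRNA pair is never a module. Mutual exclusivity is a
*set-level* property: the full member set forms a clique in exactly one
network of the collection (`host_count = 1`). Individual miRNAs may well
belong to modules of several groups — the bundled reference module table
shows per-miRNA multiplicities up to 5 — so the census checks pairwise
connectivity, not mere membership.

Significance: each exclusive candidate is scored against a null in which
every other network is replaced by a degree-preserving rewiring (double
edge swaps, 10·E attempts) and the p-value is the add-one fraction of
replicates in which the candidate re-forms as a clique in at least one
rewired non-host network. Since rewiring preserves node sets, networks
missing a member can never host the clique; such networks are skipped
exactly, and a candidate whose members never co-occur elsewhere keeps the
add-one floor `1/(n_perm+1)` without simulation. Replicates are shared
across candidates (each network rewired once per replicate), which leaves
the per-candidate distribution unchanged while doing the rewiring work
once. Benjamini–Hochberg correction is applied across all tested
candidates; modules with q <= alpha are reported, nested reported modules
of the same group are collapsed to the maximal one, and the report is
ranked by (q, density desc, size desc) under total orders, so a fixed seed
reproduces the report byte for byte.

**Interpretation of the p-value.** The p-value is the estimated
probability that degree-preserving chance alone would re-create the
module's connectivity in some other network that contains its members. It
is a *conditional* exceedance probability: candidates are only tested when
observed-exclusive, and that selection favours cliques whose re-formation
probability is low. Under a null where all networks are independent
rewirings of one template, the p-values of chance-exclusive candidates
therefore concentrate well below uniform rather than distributing
uniformly; the package's tests assert the property the estimator actually
has — agreement with an independent Monte-Carlo estimate of the
reappearance probability — and users should read q-values as ranking
evidence of non-random exclusivity, not as calibrated error rates against
an i.i.d. null. The host-count filter, not the p-value, is what keeps
fully shared structure out of the report.

The "unique miRNAs per group" step is exposed as an optional candidate
filter (`unique_filter`), off by default: reported reference modules
contain many non-unique miRNAs, so uniqueness cannot be a hard
requirement; as a filter it restricts candidates to cliques containing at
least one group-unique member.

## Synthetic worlds

Two independent generators decouple failure modes.

`simulate_ontology_world()` builds one layered random DAG per namespace
(single root, layer widths growing by a branching factor, each non-root
term drawing 1–2 parents from the layer above — acyclic by construction)
and annotates genes to random leaf terms; it exercises the OBO round-trip,
IC computation and both similarity measures end to end.

`simulate_association_world()` plants similarity *scores* directly,
bypassing the GO path, so the module-recovery test is sharp: each group
receives one planted module of group-exclusive miRNAs with pairwise
weights in [0.95, 1]; a background pool shared by **all** groups carries
mid-range weights in [0.6, 0.9]; per-group filler miRNAs have only
sub-threshold (< 0.6) similarity and vanish from the pruned networks.
Defaults are 10 groups, 60 miRNAs per group, a 30-miRNA background, module
sizes cycling 3–6, and four source dialects with ~15% cross-source
duplicate injection so deduplication is always exercised. Full background
sharing models the ubiquitously associated miRNAs observed across real
neoplasm groups; it is also what makes the null calibration meaningful —
partial sharing lets per-network percentile cutoffs act on different node
sets, manufacturing exclusive-by-membership background cliques that are
artifacts of the generator rather than signal. Partial sharing remains
available (`background_membership < 1`) as a sensitivity knob. The
generator refuses parameter combinations whose planted cliques cannot fit
inside the top decile of their network (a size-6 module needs 15 retained
edges, which a small background cannot provide).

What passing these tests shows: the pipeline recovers planted exclusive
cliques with precision and recall 1.0 on the default world (20 seeds,
`n_perm = 199`) and reports nothing on 100 of 100 null worlds. What it
does not show: robustness to correlated noise in real similarity scores,
to miRNA name inventories resembling miRBase, or to GO topologies with
realistic depth and fan-out — the synthetic DAGs are layered and shallow,
and planted weights are cleanly separated where real score distributions
overlap.

## Numerical choices and degenerate inputs

* Percentile pruning: nearest rank, strict above, ties dropped; an
  all-tied network prunes to empty, and pruning an already-pruned network
  is an error rather than a silent re-prune.
* Hypergeometric tails use the exact distribution function; p-values are
  floored at the smallest positive double before taking logs.
* Empty structures are values, not errors, where the contract allows
  (empty association file, empty network clustering average 0 with a
  warning); they are errors where silence would corrupt results (empty
  BMA matrix, empty target set, unannotated gene, empty universe).
* All stochastic steps (generators, rewiring) consume explicit integer
  seeds; iteration orders are total (sorted nodes, lexicographic clique
  keys), so equal seeds give byte-identical outputs across platforms.
* Problem sizes in the shipped tests — ontologies of <= 20 terms for
  oracle comparisons, 500-node graphs for topology checks, the default
  synthetic world for recovery — were chosen so the full suite exercises
  every code path in well under a minute per module while keeping every
  statistical check at its stated confidence.

## Known limitations

* The asymmetric similarity is an approximation realizing the two
  documented features of the published measure, not a port of it; scores
  are not comparable to the original tool's output.
* Exclusivity is defined within the supplied network collection; adding a
  group can only remove modules, never add to their hosts.
* The permutation p-value is conditional on observed exclusivity (see
  above) and `n_perm` bounds its resolution at `1/(n_perm+1)`.
* Disease-term mapping is exact-match after normalization; fuzzy or
  ontology-driven matching of disease labels is out of scope.
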