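---
title: "pathcell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathcell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pathcell analyses single-cell expression matrices at the level of pathways
rather than genes: gene sets are scored per cell with a rank-based
recovery-curve statistic (AUCell), cells are clustered and embedded in the
resulting pathway-score space, clusters are annotated against marker
signatures, and the surrounding toolkit supplies group statistics, enrichment
plots, palettes and identifier conversion. This vignette records the models,
the tunable parameters, and the design decisions behind each component, so a
reader can judge what the package computes and what its tests do and do not
demonstrate.

## AUCell scoring

For one cell, genes are ranked by decreasing expression (rank 1 = highest).
For a gene set with $m$ members present in the matrix and a rank cutoff
$T = \max(1, \lfloor qG \rfloor)$ over $G$ genes, the recovery curve
$R(k)$ counts set members with rank $\le k$. The score is the normalised
area

$$
\mathrm{AUC} \;=\; \frac{\sum_{k=1}^{T} R(k)}{\sum_{k=1}^{T} \min(k, m)}
\;\in\; [0, 1],
$$

so 1 means the set occupies the very top of the cell's ranking and 0 means no
member appears above the cutoff. Because the statistic depends only on ranks,
it is invariant under any strictly monotone per-cell transform of expression
— normalisation choices upstream do not alter it.

Choices a user can change, with defaults:

* `q = 0.05` — the top fraction of the ranking examined. This is the
  customary AUCell operating point; small `q` emphasises a cell's most
  highly expressed genes, large `q` approaches a whole-ranking AUC.
* `tie_rule = "seeded_shuffle"` — single-cell counts are zero-inflated, so
  ties are endemic. The default applies a seeded random gene permutation
  before a stable sort, which is unbiased yet exactly reproducible;
  `"stable_index"` (input gene order) is offered because it makes tiny
  examples hand-checkable.
* `min_set_genes = 1` — the engine itself accepts any non-empty
  intersection; database-scale runs are expected to pre-filter set sizes
  through the collection filters (the CLI uses 10–500).
* The maximal-area normalisation above is one of several possible
  conventions; it is fixed, documented here, and pinned by an independent
  brute-force oracle (`oracle_score_set()`, an explicit $k$-loop sharing no
  code with the vectorised engine) that the test suite compares against on
  hundreds of randomised cases at $10^{-12}$ tolerance. Genes in a set but
  absent from the matrix are intersected away; no absent-gene penalty is
  applied.

## Gene-set collections and the ontology graph

Collections load from GMT (id, description, genes), from minimal GAF 2.x
association files (symbol, qualifier, term, aspect; `NOT` rows dropped,
evidence codes not filtered), or are built in code. The ontology loader
recognises the OBO 1.2 subset `[Term]`/`id`/`name`/`is_a`/`is_obsolete`;
`relationship:` lines such as `part_of` are deliberately ignored — the
category-level filtering the package supports is an `is_a` notion — and a
plain TSV edge list is accepted as a neutral alternative for hierarchies
that are not distributed as OBO.

Pruning removes obsolete terms *with their incident edges*: children of a
pruned term become roots, and grandchildren are **not** reattached to
grandparents. Reattachment would silently assert transitive relations the
source ontology no longer states; orphaning is the conservative reading, it
is documented, and a test pins it. After pruning, descendant and ancestor
closures are indexed once (reverse-topological accumulation) so subtree
filters are lookups; the closures are verified against a brute-force DFS
oracle on random DAGs of up to 200 terms.

Filters compose conjunctively (size bounds, subtree membership under given
roots, end-level/leaf-only) and are idempotent and order-independent for
independent criteria — both properties are tested.

## The pathway-space pipeline

`run_pathway_pipeline()` executes: library-size normalisation (per-cell
scaling to 10,000 counts then `log1p`; conventional, and immaterial to the
rank-based scores themselves, but it keeps the gene-space comparison arm
honest) → AUCell scoring → per-set z-standardisation (sample sd, zero-sd
rows to 0, clipped at ±10) → PCA (`n_pcs = 50`, lowered with a warning when
fewer sets are available) → clustering → optional seeded 2-D UMAP.

* Whether pathway scores should be standardised before PCA is genuinely
  open; `zscore_per_set` is the default because raw AUC magnitudes scale
  with set size, which would otherwise dominate the leading components.
* Clustering defaults to a symmetrised Euclidean k-NN graph
  (`k_neighbors = 20`) partitioned by Leiden (modularity objective,
  `resolution = 0.8`), matching current single-cell practice; seeded
  k-means is retained as the exactly-testable path and is what the
  blob-recovery test asserts ARI = 1 on. Leiden on sparse k-NN graphs may
  refine large homogeneous groups into sub-communities; the tests therefore
  assert determinism and blob purity for Leiden, and exact recovery for
  k-means.
* UMAP is treated purely as an embedding contract: 2-D, deterministic given
  the seed. No numeric assertion is made on coordinates.
* Every stage records a content hash of its inputs. Passing a previous
  result as `cache` re-executes only stages whose input hashes changed —
  mutating the expression matrix invalidates everything downstream of
  normalisation, while changing only the clustering parameters re-runs only
  clustering. This conditional re-execution is tested both ways.
* All randomness flows from one run-level seed through named per-stage
  substreams, so adding or skipping a stage never perturbs another stage's
  draws.

## Cluster annotation from marker signatures

Marker signatures are scored per cell like any other gene set. For each
signature the per-cluster mean score is z-scored *across clusters* (the
heatmap convention: sample sd, constant rows to 0), and each cluster is
assigned the signature with the largest z, ties broken lexicographically for
determinism. An optional `min_z` leaves weak clusters unassigned; the
default assigns always, because a minimum-acceptance threshold is a
judgement the analyst should make while looking at the ranked table
(`annotate_clusters()` returns the full top-`k` per cluster, not just the
winner).

A caveat this vignette should state plainly: z-scoring across clusters is
scale-free, so a signature whose cluster means are *flat except for noise*
still produces z values of order 1. Real marker databases are informative
precisely because irrelevant signatures are not flat noise — they have
coherent variance concentrated in their own cell types. The synthetic
distractor signatures mirror this (see below).

## Group statistics, waterfall and enrichment curves

`group_metric()` computes per-feature group means, medians, z of group means
across groups, one-vs-rest `log2((m_in + p)/(m_out + p))` fold changes
(pseudocount `p = 1`, standard stabilisation), and one-vs-rest Welch t
statistics. `proportion_positive()` is the fraction of cells strictly above
a threshold (default 0). `waterfall_rank()` orders features by a two-group
contrast and flags the top 20 by absolute value for labelling (clamped to
the feature count; ties by id).

`gsea_running_score()` implements the Broad-style walk down a
descending-ordered statistic: hits add $|s|^p / \sum_{hits} |s|^p$
(`weight_p = 1`; 0 gives the classic unweighted walk), misses subtract
$1/(G - m)$; the enrichment score is the maximal signed deviation and the
leading edge collects hits at or before the extremum. The curve ends at
exactly 0 and $|ES|$ equals the curve's maximal absolute value — both are
asserted. Significance is the two-sample Kolmogorov–Smirnov test comparing
set-gene rank positions against non-set positions (asymptotic p), which is
the test named for this plot style; phenotype-permutation GSEA with FDR
q-values is out of scope.

The default two-group feature test is the Wilcoxon rank-sum test (normal
approximation with continuity correction — the single-cell convention),
with Welch's t selectable; star codes follow the four-tier convention
(`*` < 0.05 through `****` < 1e-4). No multiple-testing correction is
applied by default; Benjamini–Hochberg is available via `adjust = TRUE`.
The suite calibrates the null: over 2,000 null features the 5%-level
rejection rate must land in [0.03, 0.07].

## Palettes and color blending

Seven preset families (`default`, `light`, `red`, `yellow`, `green`,
`blue`, `purple`) are defined as constraint boxes in LCh: the first two
span the full hue circle at moderate versus high lightness; the five
specialised families confine hue to one region. `generate_palette()` draws
a dense seeded sample of a box, keeps the sRGB-representable points
(detected by Lab→RGB→Lab round-trip error, since the converter clamps),
runs k-means with `n` centres in CIELAB, and snaps each centre to its
nearest in-gamut sample — so every emitted color provably satisfies its
box. Output is hue-sorted and fully determined by the seed; presets are
generated once per `(family, n)` with a fixed per-family seed and cached.
A Monte-Carlo test requires the k-means palette's minimum pairwise ΔE to
beat the 95th percentile of random same-box draws.

Two blending modes map up to three per-cell features (each clipped at the
0.99 quantile then min-max scaled — single-cell expression has heavy upper
tails) to colors:

* **RGB**: scaled features are the R, G, B channels; zero signal is black,
  brighter is more.
* **RYB**: scaled features form a red/yellow/blue coordinate in $[0,1]^3$,
  mapped to RGB by trilinear interpolation over 8 configured corner colors;
  zero signal is the white corner, deeper color is more signal. Pure RYB
  primaries serve data visualisation poorly — yellow is too light, blue too
  dark — so the shipped primaries are tuned (yellow toward gold, blue
  toward azure), and the secondaries were chosen so that *luminance
  strictly decreases along every cube edge*. A corner table is validated on
  a dense grid at construction: any table for which increasing a coordinate
  can lighten the output is rejected. The 8 corners are reproduced exactly
  and interpolation is continuous with a bounded Lipschitz constant; both
  are asserted.

## The synthetic-data generator

`simulate_dataset()` is first-class, tested code, and every planted
condition below is a field of `synthetic_spec()`, not a constant. Defaults
describe the reference fixture used throughout the tests: 2,000 genes ×
2,000 cells, 3 cell types, 6 disjoint 50-gene "program" blocks (each type
activates two), negative-binomial counts (baseline mean 0.5, dispersion 2)
with the active programs' means multiplied by 4, 30% extra dropout zeros,
and — when enabled — a batch effect that multiplies the means of a random
20% of *non-program* genes by 2, independently per batch. Restricting the
batch effect to non-program genes is deliberate: it makes "gene-space
clustering is confounded while pathway-space clustering is conserved" a
testable inequality (pathway-space ARI against planted types ≥ gene-space
ARI, with pathway-space ARI ≥ 0.8 on the reference fixture).

The marker GMT contains one true signature per type (the first 20 genes of
each of its programs) plus 9 distractor signatures. Distractors are
*composite* signatures: each draws its genes from the deeper halves of two
program blocks belonging to **different** types. This emulates the
structure of real marker databases, where signatures for absent-but-related
cell types share pathways with several present types and therefore have
coherent, spread-out score profiles. Unstructured random distractors were
rejected at design time: their cluster-mean profiles are flat up to noise,
and the scale-free z inflates that noise into spurious winners — an
adversarial condition real marker collections do not exhibit (and one the
annotation method is documented not to handle).

What the generator does *not* emulate: library-size heterogeneity across
cells, UMI sampling, doublets, gene–gene correlation beyond the block
programs, or continuous (trajectory-like) states. Passing tests therefore
demonstrate correctness of the computations and recovery under clean
planted structure, not performance on real tissue data.

`simulate_ontology()` builds balanced binary `is_a` trees under a single
root (branch subtree size $2^{\text{depth}} - 1$, closed form used in
tests), attaches random gene sets to leaves, and can flag a fraction of
terms obsolete for pruning tests.

## Identifier mapping

Mapping tables are plain local TSVs — conversions run offline by design.
`map_ids()` is order-preserving with an explicit ambiguity policy (`first`
= lexicographically first target, `all` = full expansion with provenance,
`drop_ambiguous`), and always reports unmapped/ambiguous counts rather than
failing. Matrix conversion across species aggregates many-to-one collisions
by `sum` (count semantics, the default) or `mean` (appropriate for
normalised data); with a total, onto map and sum aggregation per-cell
column sums are conserved exactly, which is tested.

## Problem sizes and determinism

The reference fixture (2,000 × 2,000 cells, one pathway-space and one
gene-space pipeline) runs in well under a minute on one core; the
annotation stability study uses 20 seeds at 500 cells; the null calibration
uses 2,000 features at 30 + 30 cells. These sizes were chosen as the
smallest at which the planted-recovery properties are stable, keeping the
full suite fast enough to run routinely. Every stochastic component —
simulator, tie shuffling, k-means, Leiden, UMAP, palette sampling — draws
from named substreams of a single seed, and identical inputs plus seeds
reproduce results bit-identically (floating-point tolerance $10^{-8}$ on
PCs across platforms).

## Known limitations

* AUCell inherits sensitivity to the number of genes detected per cell and
  works best for sets within moderate size ranges; matrices with extreme
  per-cell detection differences will leak that structure into scores.
* The annotation statistic assumes marker signatures with structured score
  profiles (see above); it has no reject option unless `min_z` is set.
* Leiden community structure on k-NN graphs can split large homogeneous
  populations; use k-means when the expected cluster count is known and
  exact recovery matters.
* The OBO/GAF readers implement documented minimal subsets, not the full
  specifications; hierarchies with essential non-`is_a` semantics should be
  supplied as TSV edge lists expressing the intended relation.
* No batch *integration* is performed; the pipeline's robustness comes from
  scoring, not correction, and a strong batch effect on program genes will
  propagate into pathway space.
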