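# pathcell

Pathway-level analysis, scoring and annotation for single-cell expression
data.

Standard single-cell workflows cluster cells on gene expression, which makes
them sensitive to expression fluctuations, batch-specific genes and
uncharacterised transcripts. pathcell implements the pathway-centric
alternative: score curated gene sets per cell with the rank-based AUCell
statistic, then run the familiar pipeline — PCA, neighbours, clustering,
UMAP — on the resulting *pathway score × cell* matrix instead of the gene
matrix. Around that core it provides ontology-aware gene-set management,
semi-automated cluster annotation from marker signatures, the group
statistics behind heatmaps/violins/waterfalls/GSEA plots, professional
categorical palettes with RGB/RYB multi-feature blending, offline identifier
and cross-species conversion, and a synthetic-data generator so everything is
testable without downloads. It is aimed at computational biologists analysing
scRNA-seq matrices in R, and ships a `pathcell` command-line interface for
scripted use.

## The statistic at the core

For one cell, rank all $G$ genes by decreasing expression. For a gene set
with $m$ members present and rank cutoff $T = \max(1, \lfloor qG \rfloor)$
(default $q = 0.05$), the recovery curve $R(k)$ counts set members at rank
$\le k$, and the score is the normalised area under it:

$$\mathrm{AUC} = \frac{\sum_{k=1}^{T} R(k)}{\sum_{k=1}^{T} \min(k,m)} \in [0,1].$$

Scores depend only on ranks, so they are invariant to any monotone per-cell
normalisation. A brute-force oracle implementation is included and the test
suite holds the vectorised engine to it at $10^{-12}$ on hundreds of
randomised cases.

## Worked example

```r
library(pathcell)

# a synthetic dataset with 3 planted cell types, 6 pathway programs and a
# batch effect confined to non-program genes
bundle <- simulate_dataset(synthetic_spec(batch = "nonprogram_shift", seed = 1))
bundle
#> <synthetic_bundle> 2000 genes x 2000 cells, 3 types, 2 batches, 36 program sets, 12 marker signatures

# cluster cells in pathway space
cfg <- pipeline_config(embed = "none", seed = 1)
fit <- run_pathway_pipeline(bundle$counts, bundle$programs, cfg,
                            aucell = aucell_params(seed = 1))
fit
#> <pathway_space> 2000 cells, 36 features, 35 PCs, 3 clusters

# the same pipeline on gene expression, for comparison
gene_fit <- run_pathway_pipeline(bundle$counts, config = cfg,
                                 feature_space = "gene")

mclust::adjustedRandIndex(fit$labels, bundle$cell_types)
#> [1] 1
mclust::adjustedRandIndex(gene_fit$labels, bundle$cell_types)
#> [1] 0.5708821
```

The pathway-space clustering recovers the three planted types exactly
(adjusted Rand index 1.0) while gene-space clustering is dragged below 0.6 by
the batch effect — the package's headline behaviour.

Annotation against marker signatures:

```r
marker_scores <- score_collection(bundle$counts, bundle$markers,
                                  aucell_params(seed = 1))
stats <- cluster_signature_matrix(marker_scores, fit$labels)
annotate_clusters(stats, top_k = 3) |> head(3)
#> # A tibble: 3 × 6
#>   cluster  rank signature         z   mean assigned
#>   <chr>   <int> <chr>         <dbl>  <dbl> <lgl>
#> 1 1           1 type2_markers 1.15  0.197  TRUE
#> 2 1           2 distractor08  0.585 0.0930 FALSE
#> 3 1           3 distractor06  0.567 0.0921 FALSE
```

Each cluster's top-ranked signature names its planted type. A two-group
waterfall with the default labelling of the top 20 features:

```r
wf <- waterfall_rank(as.matrix(marker_scores), bundle$cell_types,
                     group_a = "1", group_b = "2", metric = "mean_diff",
                     top_n = 5)
sum(wf$labeled)
#> [1] 5
autoplot(wf)   # waterfall bar plot with the flagged features named
```

Palettes and blending:

```r
preset_palette("green", 5)
#> [1] "#7E8316" "#8DA66E" "#516F39" "#56942E" "#11A15F"
blend_ryb(list(c(0, 1), c(0, 0), c(0, 0)), q_hi = 1)
#> [1] "#FFFFFF" "#E63338"   # no signal is white; pure first channel is the tuned red
```

The same operations are available from the shell:

```sh
pathcell simulate --out sim/ --seed 1
pathcell cluster  --expr sim/matrix.mtx --sets sim/programs.gmt --out clu/ --seed 1
pathcell annotate --scores scores.tsv --labels clu/labels.tsv --out annotation.tsv
pathcell palette  --family green --n 12
```

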