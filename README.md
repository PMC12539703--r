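# glioscape

Regional analysis of 10x-Visium-style spatial transcriptomics sections from
glioma-bearing brains.

Spot-based spatial transcriptomics of a glioma-bearing section mixes tumor
cells, reactive glia and brain tissue at every capture spot. The biology —
reactive astrocytes forming a "glial scar" ring around the tumor, neuron
loss inside the core, cell–cell associations that differ between core and
periphery — is *regional*, so glioscape stratifies every spot into tumor
core (TC), tumor periphery (TP), border (BO) or non-tumor brain (BR) and
conditions all downstream statistics on those strata:

* **Segmentation** — clusters (SNN + Leiden on Marchenko–Pastur-selected
  principal components of cv²-selected variable genes) are combined with a
  tumor marker score and hex-lattice morphology (BFS ring growing on the
  Visium lattice) into a reproducible TC/TP/BO/BR labelling.
* **Regional differential expression** — per gene, the rank-sum AUC
  `U/(n_A·n_B)` between adjacent regions with exact or tie-corrected
  p-values, log2 fold-changes, BH adjustment, and preranked GSEA (weighted
  Kolmogorov–Smirnov running sum, gene-sampling permutation null).
* **Regional interactome** — Spearman gene-pair correlations per region,
  and the Fisher-transformation test
  `z = atanh(ρ)`, `(z₁−z₂)/√(1/(n₁−3)+1/(n₂−3))` for whether a pair's
  correlation differs between regions.
* **Bootstrap co-occurrence** — resample spots with replacement (B = 1000),
  average the Pearson matrix over replicates, flag pairs whose percentile
  `(α/2, 1−α/2)` CI excludes zero (α = 0.05), and compare regions through
  the difference of bootstrap means with a paired-replicate CI.
* **Cross-dataset similarity** — scaled (gene-wise z) cosine similarity of
  query cluster profiles to reference region profiles, plus dot-plot
  statistics (percent expressing, mean expression).
* **Synthetic sections** — a ground-truthed generator (concentric regions
  on the hex lattice, negative-binomial counts with planted gene programs,
  per-region Gaussian cell-type signals with planted covariances) that
  exercises every stage without external data.

See `vignettes/glioscape-methods.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(glioscape)
library(SummarizedExperiment)

se <- generateSection(SectionConfig(seed = 1))   # 140 genes x 1800 spots
se <- logNormalize(se)                           # ln(1 + c/total * 1e4)
se <- scaleGenes(se)
hvg <- selectHVG(se, nTop = 60)
pca <- pcaMP(se, genes = rownames(hvg)[hvg$selected], kMax = 20)
pca
#> SpotPCA: 1800 spots x 60 genes
#>   MP upper edge: 1.413 | components retained: 2
```

Two components sit above the Marchenko–Pastur noise edge — the planted
regional structure. Cluster, score and segment:

```r
cl <- clusterSpots(pca, kNeighbors = 15, resolution = 1, seed = 1)
score <- markerScore(se, grep("^Tum", rownames(se), value = TRUE))
se <- segmentRegions(se, cl, score)
table(truth = colData(se)$truth_region, predicted = regionLabels(se))[1:4, 1:4]
#>      predicted
#> truth   TC   TP   BO   BR
#>    TC  127    0    0    0
#>    TP    0   90    0    0
#>    BO    0    0  114    0
#>    BR    0    0    0 1469
```

The planted concentric labels are recovered exactly on this section.
Differential expression across the scar boundary ranks the planted
border-enriched ("scar") program on top:

```r
de <- wilcoxAUC(se, c("BO", "BR"))
head(as.data.frame(de[order(de$q), c("auc", "log2fc", "p", "q")]), 3)
#>              auc   log2fc            p            q
#> Scar10 0.9654796 2.690195 9.786934e-62 1.370171e-59
#> Scar02 0.9615653 2.758048 9.860790e-61 6.365643e-59
#> Scar08 0.9610130 2.689429 1.364066e-60 6.365643e-59
```

An AUC of 0.97 means a random BO spot out-expresses a random BR spot 97%
of the time. Bootstrap co-occurrence of the cell-type signals recovers the
planted astrocyte–tumor association in the periphery and its absence in
the core:

```r
sig <- metadata(se)$truth_signals[colnames(se), ]
cooc <- cooccurrenceByRegion(sig, colData(se)$truth_region,
                             regions = c("TC", "TP"), B = 1000, seed = 1)
differentialCooccurrence(cooc$TP, cooc$TC)
#>   signal1 signal2 regionA regionB       delta       ciLow    ciHigh excludesZero
#> 1   astro   micro      TP      TC  0.17908653 -0.08907984 0.4685920        FALSE
#> 2   astro   tumor      TP      TC  0.71890627  0.51706139 0.9241672         TRUE
#> 3   micro   tumor      TP      TC -0.03263482 -0.30913863 0.2241036        FALSE
```

Only the planted astro–tumor difference (0.6 in TP vs 0.0 in TC) has a
difference CI excluding zero. `runPipeline()` chains all stages from one
seeded config and writes provenance-stamped TSVs plus a hash manifest.

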