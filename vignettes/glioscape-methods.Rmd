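---
title: "Regional statistics for glioma-bearing spatial transcriptomics sections"
author: "glioscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional statistics for glioma-bearing spatial transcriptomics sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spot-based spatial transcriptomics of a glioma-bearing brain section captures
a mixture of tumor cells, reactive glia and residual brain tissue at each
~55 µm capture spot on a hexagonal lattice. The biology of interest is
*regional*: tumor-associated astrocytes form a reactive ring (the "glial
scar") around the tumor core, neurons are lost inside the core, and
cell–cell associations differ between the core and its periphery. glioscape
organizes the analysis around four spot strata — tumor core (TC), tumor
periphery (TP), border (BO) and non-tumor brain (BR) — and conditions every
downstream statistic on them.

All data live in a `SpotExperiment`, a `SingleCellExperiment` subclass with
genes in rows and spots in columns; array coordinates, tissue flags, region
labels and cluster assignments live in `colData()`. On-disk interchange uses
the 10x conventions (genes × spots MatrixMarket, barcodes/features tables,
`tissue_positions` CSV).

# Hex-lattice geometry

Spots occupy array coordinates `(row, col)` with `row + col` even; the six
neighbors are `(row ± 1, col ± 1)` and `(row, col ± 2)`. Mapping
`u = (col + row)/2`, `v = (col − row)/2` turns this into the standard axial
hexagon, giving a closed-form distance used by the generator and as a test
oracle. All *analysis* distances, however, are BFS step counts restricted to
in-tissue spots (`hexBFS()`): tissue holes and irregular boundaries then
behave correctly, and a brute-force BFS is its own specification.

# The synthetic section generator

`generateSection()` builds a ground-truthed caricature of a coronal
glioma-bearing section:

* **Geometry.** A full rectangular lattice with a concentric truth
  labelling: TC within `coreRadius` hex steps of the center (default 6),
  then a TP rim of `tpWidth` rings (default 2) completing the tumor mass, a
  BO ring of `boWidth` rings (default 2), and BR elsewhere. Real scar
  thickness is qualitative only, so the widths are configurable; the
  defaults of two rings keep all four strata populated at modest grid
  sizes.
* **Counts.** Per-gene spatial structure comes from *programs*: a
  core-enriched tumor program, a BO-enriched reactive ("scar") program, a
  uniform program, and a core-depleted neuronal program whose TC multiplier
  is exactly zero. Within a region, a gene's expected share of the library
  is proportional to `base × multiplier`, normalized so the expected spot
  total equals the spot's library size. Library sizes are log-normal
  (default meanlog `log(5000)`, sdlog 0.35 — typical Visium depth
  heterogeneity) and counts are negative binomial with dispersion
  `theta = 2` (variance `mu + mu²/theta`), the standard overdispersed model
  for spot data.
* **Cell-type signals.** Latent per-spot Gaussians, drawn per region with a
  configurable mean vector and covariance matrix (positive semidefiniteness
  is validated). Keeping them latent — not derived from the counts — makes
  the co-occurrence ground truth exact. The default means mirror the
  expression programs on a z-like scale (tumor signal high in TC/TP,
  astrocyte signal peaking in BO and *negative* in TC, where the counts are
  dominated by the tumor program), so that marker-score signals computed
  from the counts correlate strongly with the latent truth; default
  within-region variance is 0.5, making regional structure dominate local
  noise. The default correlations plant an astrocyte–tumor co-occurrence of
  0.6 in TP and 0.0 in TC, the structure the differential co-occurrence
  analysis is designed to detect.

What the generator does *not* emulate: histology, spatial autocorrelation
beyond region blocks (no smooth gradients), multi-sample batch structure,
or segmentation errors in the truth labels. Passing the planted-truth tests
therefore demonstrates correctness of the statistical machinery under the
stated model, not robustness to real-tissue artifacts.

# Preprocessing

* `logNormalize()`: `ln(1 + count/total × 10⁴)` (pseudocount 1, scale
  factor 10,000 — the field's conventional normalization defaults).
  Zero-total spots are excluded with a warning.
* `scaleGenes()`: per-gene z-scores, zero-variance genes mapped to 0,
  clipped at ±10.
* `selectHVG()`: the squared coefficient of variation `cv² = var/mean²` per
  gene, with the mean-dependent baseline `cv²(m) = a₁/m + a₀` fitted by
  ordinary least squares over genes with `mean ≥ 0.05`; genes are ranked by
  observed/fitted ratio. The χ²-significance variant of this fit is
  deliberately omitted: ranking by ratio is what the selection needs, and
  the OLS fit is exactly testable (Poisson data recover `a₁ ≈ 1, a₀ ≈ 0`).
* `pcaMP()`: eigenvalues of the scaled-data covariance via economy SVD
  (handles `p > n`); the upper Marchenko–Pastur edge `(1 + √(p/n))²` with
  unit noise variance (genes are standardized first). **Finite-sample
  correction:** at realistic sizes the largest pure-noise eigenvalue
  exceeds the asymptotic edge in a non-negligible fraction of datasets
  (measured ≈7% at n = 2000, p = 100), so the default threshold adds a
  Tracy–Widom allowance at the 95% point under the Johnstone scaling
  `σ = (√(n−1) + √p)(1/√(n−1) + 1/√p)^{1/3}/n`. This keeps the
  "nonrandom component" reading of the edge honest; `twCorrection = FALSE`
  restores the plain asymptotic edge. Retention uses strict inequality and
  `kRetained = 0` is a legal, flagged result.
* `clusterSpots()`: k-nearest-neighbor graph on the retained scores,
  Jaccard-reweighted (shared/(2k − shared), pruned below 1/15), partitioned
  by the Leiden algorithm (modularity objective, `igraph`), seeded. Note
  that with Jaccard edge weights the effective resolution scale is smaller
  than conventions based on unweighted graphs: well-separated blobs merge
  into their natural clusters around resolution ≈ 0.25, while resolution
  1 oversegments; the resolution is surfaced in the output attributes so
  runs are self-describing.

# Region segmentation

Region delineation in this field is often done manually from the embedding
and spatial projection; `segmentRegions()` replaces that with a
reproducible score-plus-morphology rule, and `setRegionLabels()` accepts a
label file so a manual segmentation can be reproduced verbatim. The rule: clusters whose mean tumor
marker score exceeds 0.5 are tumor clusters; the tumor *mass* is their
largest hex-connected component (lexicographic tie-break; smaller
components are labeled EXCLUDED); TP is the inner rim of the mass within
`tpRings` of any non-mass spot, TC the remainder; BO is the ring of
non-mass spots within `boRings` of the mass; BR is everything else.
Defining TP *inside* the tumor mass (rather than as a mixed halo outside
it) was a genuinely open choice; the inner-rim reading matches the planted
geometry and is configurable through the ring widths.

# Regional differential expression and enrichment

`wilcoxAUC()` computes, per gene, the rank-sum AUC between two regions
(midranks for ties), with exact p-values when `nA·nB ≤ 10,000` and there
are no ties, otherwise the tie-corrected normal approximation with
continuity correction. The effect size is the difference of mean lognorm
values divided by `ln 2` — a log2 fold-change on the normalized scale, the
conventional effect size reported alongside rank-sum AUCs. `gseaPreranked()` runs the
weighted Kolmogorov–Smirnov running sum (weight exponent 1) on the ranking,
with a *gene-sampling* permutation null, one-sided tail p-values with +1
smoothing, and sign-matched NES normalization. fgsea's adaptive multilevel
refinement is intentionally not reproduced: simple permutation is exactly
testable, and fgsea's ES kernel serves as an independent oracle in the
test suite. The ranking statistic is the log2 fold-change; a signed
p-value statistic would be an alternative, but the effect size keeps the
ranking interpretable in expression units.

# The regional interactome

`spearmanByRegion()` computes midrank Spearman correlations per gene pair
within each region (p via the t-approximation on `n − 2` df, BH within
region). `fisherCompare()` tests equality of two correlations:
`z = atanh(ρ)`, statistic `(z₁ − z₂)/√(1/(n₁−3) + 1/(n₂−3))`. The
default reference distribution is t with `n₁ + n₂ − 6` df (the combined
Fisher-z error degrees of freedom), a slightly conservative choice at
small n; `ref = "normal"` restores the conventional standard-normal
reference. At the sample sizes
involved the two are nearly indistinguishable, and the type-I error is
verified empirically to sit at the nominal 5%. Correlations are computed on
lognorm values (not raw counts, not clipped z-scores) — the input scale was
unstated; lognorm is the least processed scale on which Spearman is still
library-size-robust, and the assay is a parameter. The BH family is always
exactly the set of rows emitted by one invocation, recorded in an output
attribute.

# Bootstrap co-occurrence

`bootstrapCooccurrence()` implements the four-step procedure: resample
spots with replacement (same size, B = 1000 by default), compute the full
Pearson matrix per replicate, average over replicates, and take the
empirical `(α/2, 1−α/2)` quantiles (α = 0.05) as the confidence bounds; a
pair is significant iff its CI excludes zero. The CI flavor is the plain
percentile bootstrap; BCa or basic intervals would be alternatives, but
the percentile form is the direct quantile reading and is what the
coverage tests calibrate. Replicates in which any signal is
constant are skipped (Pearson undefined) and counted; more than 50%
skipped is an error. Per-region streams derive from the root seed as
`seed + region index`, so each region's result is individually
reproducible. `differentialCooccurrence()` reports `Δ = mean_A − mean_B`
with a CI from index-paired replicate differences; this Δ-CI is an
extension of the four-step procedure (difference maps by themselves carry
no significance statement) and the sign convention is recorded in an
output attribute. Cell-type signals are accepted from any external spot × type
table; `markerSignalMatrix()` provides mean-z marker scores as the default
stand-in, since no specific deconvolution method is prescribed.

# Cluster-to-region similarity

`scaledCosine()` matches genes across species by uppercased symbol (an
explicit ortholog map can override), z-scales each gene across the union of
query and reference groups, and computes cosine similarity; each query
cluster is assigned the argmax reference region. "Scaled" was interpreted
as gene-wise z-scaling across all groups — the reading that makes the
similarity invariant to per-gene affine shifts applied jointly to both
sides — and can be disabled (`scale = FALSE`) to recover the raw cosine
kernel. The gene universe is whatever the two profile matrices share;
profiles restricted to HVGs simply yield a restricted universe.
`dotStats()` supplies the dot-plot backing numbers: percent of spots with
nonzero expression, and mean expression over all group spots.

# Orchestration

`runPipeline()` executes simulate → preprocess → segment → DE → GSEA →
interactome → co-occurrence → similarity from a single validated config
(`validateRunConfig()` aggregates all range errors and requires an explicit
seed), writes every table as tidy TSV with a provenance comment line
(package version + config hash), and finishes with a manifest of file
hashes; deterministic stages reproduce bit-identically.

# Numerical and testing notes

* Degenerate inputs have explicit policies throughout: zero-variance genes
  z-score to 0; self-pairs and |ρ| = 1 are reported as degenerate rather
  than tested; empty regions yield `n = 0` rows; a tumor-free section is
  all-BR with a warning.
* Quantiles are R's default type 7 everywhere, which keeps the
  differential co-occurrence CI exactly antisymmetric under swapping the
  regions.
* The test suite checks the statistical machinery at deliberately modest
  problem sizes — sections of ~1,000–2,700 spots and 50–140 genes,
  100–400 Monte-Carlo seeds per calibration claim, B = 1,000 bootstrap
  replicates — chosen so the whole suite documents calibration (type-I
  error, CI coverage, MP retention rates, planted-truth recovery) with
  binomial uncertainty small relative to the asserted bands.
* Known limitations: no spatial (block) bootstrap — spots are treated as
  exchangeable within a region; no batch integration — one section (or a
  naive concatenation) at a time; the generator's truth labels are exactly
  concentric, so segmentation accuracy on it is an upper bound on real
  performance.
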