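---
title: "Methods: spatial single-cell analysis of multiplexed TMA imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of multiplexed TMA imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialtma)
```

## Scope and model of the data

`spatialtma` analyses segmented single-cell tables from highly multiplexed
fluorescence imaging (CODEX-style cyclic staining) of tissue microarrays:
one ~1 mm core per patient, one row per cell carrying µm coordinates,
nuclear area, and median per-marker intensities, together with a clinical
table of immune-checkpoint-inhibitor response (responder R / non-responder
NR) and overall survival. The pipeline starts *after* segmentation; pixel
data, deconvolution, and segmentation itself are out of scope.

The stages are: quality filtering → normalization → batch-adjusted PCA →
graph clustering and signature-based phenotyping → tumour/margin/stroma
compartments → per-sample spatial features (proportions, pairwise proximity
densities, cellular-neighbourhood frequencies and enrichments, triplet
distance-ratio scores) → response and survival association.

## Normalization and phenotyping

Raw intensities are arcsinh-transformed, `y = asinh(x / 150)`; the cofactor
of 150 is the panel's fixed variance-stabilization constant
(`asinh(150/150) = 0.881374`). Marker columns are then z-scored across
cells, and each cell is z-scored across markers. Column scaling removes
per-marker gain; row scaling removes per-cell staining intensity. Whether
"scaling across rows" means a z-score or a unit norm is genuinely open; we
chose the z-score and note that constant rows and columns map to 0 rather
than NaN.

QC removes cells below a minimum median DAPI signal and outside the
10–220 µm² nuclear-area window (strict inequalities: areas of exactly 10 or
220 are retained). No numeric DAPI threshold is published, so the default is
data-adaptive — the 5th percentile of DAPI per core — and is logged per core;
a fixed `dapi_min` can be configured.

Clustering uses the 25-marker panel plus z-scored nuclear area, reduced to
20 principal components (the component count is not published; 20 is the
package default, with a fixed sign convention — the largest-magnitude
loading of each component is positive — for reproducibility). Batch
adjustment across cores is a *location-only* simplification of iterative
integration methods: per-core component means are centred to the global
mean. This removes exactly the scalar per-core staining shifts the synthetic
generator plants and keeps the stage contract-testable; a full integration
method can be substituted at this hook.

Phenotyping follows the Phenograph construction: k = 30 nearest neighbours
in PC space, edges weighted by Jaccard overlap of neighbour sets, Leiden
community detection (modularity objective) at resolution 2. Resolution 2
deliberately over-partitions — that is the point of the published workflow,
which merges ~55 clusters into 19 types — so cluster→type annotation doubles
as the merge step. Two consequences are tested explicitly:

* on three well-separated Gaussian blobs, resolution ≤ 0.5 recovers exactly
  three clusters (ARI 1), while resolution 2 refines them into purer
  sub-clusters, each wholly inside one blob;
* duplicating every cell is *not* partition-invariant at fixed k (a kNN
  graph is density-adaptive); invariance holds exactly when k is scaled to
  2k+1, and duplicates always co-cluster.

Annotation scores each cluster against each of the 19 canonical signatures
(mean of cluster-mean scaled expression over the signature's markers),
assigns the argmax, restricts PanCK-dominant clusters to the three tumour
subsets (HLADR⁺, CD44⁺, Ki67⁺), breaks ties toward larger signatures, and
labels clusters under a configurable score floor (default 0.5)
"unclassified". The floor separating generic CD45⁺ "lymphocyte" calls from
specific subsets is not published; it is config, not inference.

## Compartments

The published tumour/stroma mask comes from a pixel classifier on raw
PanCK fluorescence; this package re-derives it from annotated cell points,
preserving the two published rules exactly: tumour components smaller than
100 µm² are discarded, and the margin is the 30 µm Euclidean dilation of the
tumour minus the tumour. Tumour-typed cells are stamped as 5 µm discs
(sub-pixel exact) on a 2 µm raster, closed morphologically with a 10 µm
radius (about one cell diameter), and labelled by 8-connectivity. Distances
are true Euclidean distances via an exact distance transform, so the annulus
around a 50 µm tumour disc has area within 5% of π(80² − 50²). Halving the
raster pixel changes labels only in a one-pixel band along the mask and
margin contours (mean disagreement below 1% on nested-geometry cores).

## Spatial features

*Proximity density* for a type pair (A, B) in a sample is the number of
unordered A–B cell pairs within 20 µm (boundary inclusive), divided by
|A| + |B| (|A| for a same-type pair; self-pairs excluded, each unordered
pair counted once — same-type normalization conventions differ by a constant
factor and this one is fixed and logged). The radius-mode semantics are
primary; the published call also passes `knn = 3`, which is inert in radius
mode. Scores computed with the grid index are contractually equal to the
O(n²) scan and this is tested on random samples.

*Cellular neighbourhoods*: each cell's window is itself plus its 9 nearest
neighbours within the same sample (total 10, matching the reference
implementation where self is the first neighbour; a strict exclude-self
flag exists). Window composition vectors are pooled and k-means clustered
(k = 10, 10 restarts, fixed seed) — "unsupervised KNN algorithm" in the
source text is read as k-means of window vectors, which is what the cited
pipeline does. Per-sample neighbourhood frequencies feed group t-tests.
Differential within-neighbourhood enrichment uses
`e = log2((f_snc + ε)/(f_sc + ε))` per sample and an OLS fit `e ~ group`;
the richer covariate structure of the original enrichment model is not
recoverable from the text, so this fixed OLS form is the package's
documented choice (ε = 10⁻³ keeps everything finite).

*Triplet spatial score*: for each center cell of type C, the ratio of the
distance to the nearest tumour cell (D2) over the distance to the nearest
partner cell of type P (D1), averaged per sample. Higher values mean the
partner sits closer than the tumour — the immunosuppressive direction for
macrophage partners. The orientation (D2/D1), the center/partner role
assignment, and mean aggregation are fixed choices with flags for the
inverse, the symmetric variant, and the median. Coincident points use a
0.2 µm distance floor. The score is invariant to rigid motions and uniform
scaling, and adding a partner cell can only increase ratios; both are
tested.

## Outcome statistics

All feature families flow through one harness. Group differences use Welch
t-tests (the unequal-variance choice where the source says only "t-tests"),
log2 fold changes oriented NR over R, unadjusted p-values primary with BH
q-values alongside. Survival uses Cox proportional hazards on z-scored
features (hazard ratios per SD, Efron ties — note the duplication-invariance
caveat: exact invariance would require Breslow) and median-cut Kaplan–Meier
with ties assigned to "low". Logistic response models report in-sample AUC
(deliberately optimistic, as in the source analysis), with perfect
separation flagged rather than failing, and an optional leave-one-out AUC.
Cell-type proportions use typed cells as the denominator ("total cell
count" is ambiguous given ~10% unphenotyped cells; the typed-cell choice is
flagged here).

## The synthetic cohort generator

The generator is first-class, tested code that emulates the cohort the
statistics were developed on: ~35 one-millimetre cores (14 R / 21 NR at
full scale; tests default to 8–32 cores of 1000–3000 cells, the desk
scale), 19 cell types at realistic baseline proportions, three tumour nests
of radius 120 µm holding 90% of tumour-typed cells, lognormal marker noise
(sdlog 0.35) around signature-determined means, and per-core, per-marker
lognormal batch shifts (sdlog 0.15) that the location-centering adjustment
removes exactly. Signature means use three levels (background 10, shared
markers such as pan-immune CD45 at 120, defining markers at 300 a.u.) so
that nested signatures (lymphocyte ⊂ T-cell subsets, monocyte ⊂ macrophage)
remain separable by the annotation score.

Planted effects are explicit configuration, not defaults — the default
cohort is null:

* **abundance**: editing the per-group proportion table (e.g. doubling Treg
  in NR at stroma's expense) plants a log2 fold change of ~1;
* **attraction**: relocation thinning — for each type-A cell, with
  probability equal to the strength, one unused type-B cell is moved to a
  uniform point within the attraction radius. This is exactly controllable
  (a binomial oracle) and was chosen over a Gibbs point process for that
  reason;
* **niches**: a circular region with its own type composition and per-group
  area fraction, with per-cell membership recorded in the ground truth;
* **survival**: exponential event times with hazard
  `h0 · exp(Σ coef · feature)` on standardized true per-core type
  proportions, censored uniformly on 258–3243 days (the cohort's censor
  range); baseline hazard 1/1000 per day puts median survival near two
  years.

What the generator does *not* emulate: cell-shaped marker spillover,
segmentation errors, spatially varying staining gradients within a core,
necrosis/folding artifacts, or realistic spatial point-process parameters
for real tissue (none are published; the defaults are stated, not
estimated). A green recovery test therefore establishes that the
implementation recovers *planted* effects at stated power, not that the
cohort-specific published values are reproduced — those depend on the
deposited raw data, which this package intentionally does not require.

Everything is driven by a single integer seed: same config and seed give
byte-identical tables, and two seeded end-to-end pipeline runs produce
identical manifests (wall-clock timings are logged separately from the
manifest precisely so this holds).

## Numerical and degenerate-input choices

* Constant columns/rows under z-scoring map to 0, never NaN.
* Zero variance in both groups of a t-test reports p = 1 (equal means,
  flagged) instead of erroring.
* Missing types give missing (NA) interaction and triplet scores, never 0;
  NA features propagate and are skipped when more than half missing.
* Ties: kNN ties break by cell index; annotation ties by signature size
  then lexicographically; median-split ties go to "low".
* A core with fewer cells than a window uses all its cells (flagged);
  cores with fewer than 2 cells are excluded from batch centering.
* Packing is checked (at most 0.5 cells/µm²) before placing synthetic
  cells; nests must fit inside the core disc.

## Performance notes

Acceptance-scale loops run the heavy stages on generator-truth labels
rather than re-clustering 50 cohorts (cell typing has its own full-route
ARI ≥ 0.8 criterion), and `generate_cohort(markers = FALSE)` skips marker
simulation where only labels are consumed. kNN search, close-pair
enumeration, the exact Euclidean distance transform, and connected-component
labelling are small Rcpp kernels; everything else is vectorized R on top of
`data.table`, `igraph`, and `survival`.
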