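# spatialtma

Spatial single-cell analysis of highly multiplexed tissue-microarray (TMA)
imaging, for studies relating the tumour microenvironment to immunotherapy
outcome. The package takes *segmented* cell tables (µm coordinates, nuclear
area, median per-marker intensities from CODEX-style cyclic imaging) plus a
clinical table (immune-checkpoint-inhibitor response R/NR, overall
survival), and produces per-sample spatial features and their association
with response and survival. A synthetic-cohort generator with planted,
recoverable ground truth backs every stage's tests.

## What it computes

For each core (≈ one patient sample):

* **Phenotypes** — QC (min DAPI; nuclear area within 10–220 µm²), arcsinh
  normalization `asinh(x/150)` with column-then-row z-scoring,
  batch-adjusted PCA, Phenograph-style clustering (kNN graph, k = 30,
  Jaccard edge weights, Leiden at resolution 2), and annotation to 19 cell
  types by canonical marker signatures (e.g. Treg = CD45⁺CD4⁺FoxP3⁺CD25⁺;
  PanCK⁺ tumour cells split into HLADR⁺/CD44⁺/Ki67⁺ subsets).
* **Compartments** — a rasterized tumour mask from tumour-typed cells
  (≥ 100 µm² components kept), a 30 µm margin band by Euclidean dilation,
  and a tumour/margin/stroma label per cell.
* **Spatial features** —
  * proportions of each type per sample and compartment;
  * *proximity density*: unordered A–B pairs within r = 20 µm divided by
    |A| + |B| (pairwise interaction score);
  * *cellular neighbourhoods*: 10-nearest-neighbour composition windows,
    k-means into 10 neighbourhoods; per-sample frequencies and
    within-neighbourhood differential enrichment
    `log2((f_snc + ε)/(f_sc + ε)) ~ group`;
  * *spatial score*: per center cell of type C, `D2/D1` = distance to the
    nearest tumour cell over distance to the nearest partner cell,
    averaged per sample (higher ⇒ partner closer than tumour, the
    immunosuppressive topology for macrophage partners).
* **Outcome statistics** — Welch t-tests (log2 fold change NR/R, unadjusted
  p primary, BH q alongside), in-sample logistic AUC (uni-/multivariate),
  Cox proportional hazards per feature SD, and median-cut Kaplan–Meier with
  log-rank tests.

## Worked example

A 12-core synthetic cohort with the Treg proportion doubled in
non-responders, run through phenotyping, compartments, composition and
outcome testing:

```r
library(spatialtma)
ct <- synth_cell_types()
ct$prop_NR[ct$type == "Treg"]   <- 0.04  # doubled vs 0.02 in responders
ct$prop_NR[ct$type == "Stroma"] <- 0.13
cfg <- synth_config(n_cores = 12, responders = 6, cells_per_core = 1500,
                    cell_types = ct, seed = 42)
coh <- generate_cohort(cfg)

qc <- qc_filter_cells(coh$cells)
ph <- phenotype_cells(qc$cells, pipeline_config(seed = 42))
cc <- compartmentalize(ph$cells)
fm <- cell_proportions(cc$cells)
res <- differential_abundance(fm, coh$clinical)
head(res[order(res$p), c("feature", "log2fc", "t", "p", "q")], 4)
```

prints (26 raw clusters merge into the 19 types; ARI vs planted truth = 1.0;
compartment fractions tumour 0.264 / margin 0.130 / stroma 0.607):

```
                       feature log2fc     t        p        q
                     prop|Treg  1.017  8.25 1.85e-05 0.000351
                   prop|Stroma -0.202 -2.93 1.67e-02 0.158757
 prop|Proliferating lymphocyte -0.409 -2.41 4.59e-02 0.227627
               prop|CD4 T cell -0.181 -2.31 4.79e-02 0.227627
```

The planted 2× Treg effect is recovered at the top with log2FC ≈ 1, and
nothing else survives BH adjustment. Triplet spatial scores and survival
screens run the same way:

```r
score_panel(cc$cells)[1:3, ]
#  sample_id ss|CD4 T cell|Macrophage ss|CD8 T cell|Macrophage
#    core_01                    2.145                    2.569
#    core_02                    2.116                    2.177
#    core_03                    1.957                    2.083
survival_screen(fm[, c("sample_id", "prop|Treg", "prop|CD8 T cell")],
                coh$clinical)
#          feature    hr ci_low ci_high wald_p logrank_p
#        prop|Treg 0.822  0.412    1.64 0.5770     0.654
#  prop|CD8 T cell 3.727  1.001   13.87 0.0497     0.284
```

(Hazard ratios are per feature SD; this cohort plants no survival effect,
so these are null draws.)

An end-to-end run writing every stage output plus a deterministic manifest:

```r
run_pipeline("out_dir", cfg = pipeline_config(seed = 7), simulate = TRUE,
             synth = synth_config(n_cores = 8, responders = 4,
                                  cells_per_core = 1000, seed = 7))
```

A command-line wrapper lives at `inst/cli/spatialtma.R`
(`simulate` and `run` subcommands).

## Documentation

`vignettes/spatialtma-methods.Rmd` describes the model, every fixed
constant and its origin, what the synthetic generator does and does not
emulate, and the package's numerical and degenerate-input choices.
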