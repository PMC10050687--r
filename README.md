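# marrowatlas

Multi-sample single-cell RNA-seq analysis of bone-marrow ageing, built as a
reusable, fully tested R pipeline. It targets the workflow used to study how
the marrow changes across the human lifespan and how disease samples deviate
from it: assemble a healthy reference atlas from many donors (ages spanning
2–84 years), find age-associated shifts in cell-type composition and in gene
expression, train a transcriptomic **age clock**, and map query (disease)
samples onto the frozen reference to flag cells that look like nothing in
healthy marrow.

Because the public cohorts such analyses run on (hundreds of samples, ~10⁵–10⁶
cells) are not reproducible at desk scale, the package ships a **synthetic
cohort generator with planted ground truth** — multiplicative study batch
effects, marker-gene panels, logit-free age trends in composition, linear
age-gene slopes, and an ectopic "malignant" expression program in query
samples. Every stage of the pipeline is verified against that truth or against
independent oracles (brute-force enumeration, normal equations, exact
permutation, KKT conditions) in the test suite.

## The methods in brief

- **QC & normalisation** — explicit per-cell bounds (UMIs, detected genes,
  mitochondrial/ribosomal fractions), whole-sample removal under 200 surviving
  cells, then total-count log-normalisation:
  `x̂_gc = log(1 + c_gc / Σ_g c_gc · 10⁴)`.
- **Reference embedding** — per-sample top-3000 highly variable genes merged by
  a *consensus* rank (how many samples select each gene); per-gene
  standardisation clipped at ±10; PCA, first 30 PCs; mutual-nearest-neighbour
  batch correction in PC space; Louvain clustering on the kNN graph; Wilcoxon
  one-vs-rest cluster markers.
- **Composition trends** — per cell type, OLS of the per-sample proportion
  `x_j = β₀·Age_j + β₁·Project_j` (intercept + study dummies), overall p from
  the age coefficient's t-test, per-study Spearman correlations alongside.
- **Age genes** — pseudobulk mean of batch-corrected expression per
  (sample, cell type); eligibility: ≥ 20 samples with ≥ 20 cells, gene detected
  in > 10 % of the type's cells; Pearson correlation with age, retain p < 0.01;
  local hypergeometric over-representation analysis with BH adjustment.
- **Age clock** — per cell type, elastic-net regression (α = 0.5, λ by 10-fold
  CV at the sample level) of age on that type's age genes; a sample's predicted
  age is the **median** over its cell types; evaluated by out-of-fold
  correlation and median absolute error, with the gene screen re-run inside
  each training fold.
- **Reference mapping** — frozen-transform projection of query cells into the
  reference PC space; label transfer from the 30 nearest reference cells;
  confidence score `s_i = 1/(mean neighbour distance)`, min–max normalised to
  [0, 1]; a two-component Gaussian-mixture gate calls cells in the
  higher-mean component *confident* — low-confidence cells are candidate
  disease-specific states; Wilcoxon disease-vs-healthy DE at p < 0.05,
  |logFC| > 0.5.

## Worked example

The `analysis/` directory holds the numbered drivers (`01_simulate.R` …
`07_map_disease.R`); run them in order from the repository root. A condensed
session:

```r
library(marrowatlas)

cfg <- example_cohort_config(n_studies = 3, samples_per_study = 8,
                             n_genes = 400, mean_cells_per_sample = 250,
                             seed = 20260929)
ref <- generate_reference(cfg)
qc  <- qc_filter(ref$dataset, qc_thresholds(min_genes = 50,
                                            min_cells_per_sample = 100))
ds  <- normalize_total(qc$dataset)

hvg <- consensus_hvg(ds, per_sample_n = 150, consensus_n = 150)
em  <- scale_and_pca(ds, hvg, n_components = 30)
em$reference_embedding <- batch_correct(em$reference_embedding,
                                        ds$cell_table$study_id)
cl  <- cluster_cells(em$reference_embedding, k = 20, seed = 1)
```

Running the drivers prints, among other things:

```
Louvain: 4 clusters, modularity 0.706, ARI vs truth 1.000
  cluster annotation: 1->Tcell, 2->Bcell, 3->Mono, 4->Plasma

Cell-type composition trends (proportion change per year):
  Tcell    beta_age +0.00179 (planted +0.00150), p = 5.48e-07, BH p = 2.19e-06
  Bcell    beta_age -0.00170 (planted -0.00150), p = 4.59e-06, BH p = 9.17e-06
  Plasma   beta_age -0.00011 (planted +0.00000), p = 0.51,     BH p = 0.68

age-related genes: 99 retained at p < 0.01; sensitivity 0.99 on 75 planted

10-fold out-of-fold: r = 0.988, median |error| = 3.95 years (n = 24)

MappingResult: 1520 query cells, 94.9% confident
label accuracy (normal cells) 1.000; confidence AUROC 1.000; gate recall of abnormal 1.000
plasma DE: 286 significant genes (p<0.05, |logFC|>0.5); 100% of the planted program recovered
```

Read: the clustering recovers the four planted populations exactly; the
composition screen finds the two planted trends (±0.0015/yr) and nothing else;
the pseudobulk screen recovers 74/75 planted age genes at a ~1 % false-positive
budget; the clock predicts held-out donor ages to ~4 years median error on a
24-sample cohort; and on the query cohort the confidence gate isolates every
ectopically shifted "malignant" plasma cell, whose expression program the DE
step then recovers in full.

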