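---
title: "Methods: a verifiable bone-marrow ageing atlas, age clock, and reference mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a verifiable bone-marrow ageing atlas, age clock, and reference mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowatlas)
```

marrowatlas implements a complete multi-sample single-cell analysis of bone-marrow
ageing as a tested pipeline: a reference embedding built from many donors across a
wide age span, screens for age-associated changes in cell-type composition and in
gene expression, a per-cell-type transcriptomic age clock, and projection of query
(disease) samples onto the frozen reference with a confidence gate that flags
phenotypically abnormal cells. Because the real public cohorts this style of
analysis runs on are far beyond desk scale, the package ships a synthetic cohort
generator with planted, recoverable ground truth; every stage is verified against
that truth or against independent oracles in the test suite.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults define the study
conditions everything downstream is checked under.

**Count model.** Each cell's counts are negative binomial with fixed dispersion
0.3 (variance $\mu + 0.3\mu^2$; Poisson available via `count_model = "poisson"`).
A cell of type $t$ in sample $j$ (study $b$, donor age $a_j$) has gene-wise log
rates

$$\log \lambda_g = \beta_g + m_{tg} + s_{tg}\,(a_j - \bar a) + b_{bg},$$

where $\beta_g \sim N(0,1)$ is a baseline, $m_{tg}$ adds `marker_log_fc`
(default 2 natural-log units) on the type's marker panel, $s_{tg}$ is the planted
age-gene slope (default magnitude 0.015 per year, signs alternating), and
$b_{bg} \sim N(0, \texttt{batch\_sd}^2)$ (default SD 0.15) is a study-wise
multiplicative batch factor — the simplest effect a batch-correction step must
remove and a study covariate must absorb. Rates are renormalised so the expected
depth per cell is `sequencing_depth` (default 2,000 UMIs). A handful of genes
carry `MT-`/`RPL`/`RPS` symbols so QC fractions are exercised.

**Composition.** Ages are uniform over 2–84 years (a discrete list can be given).
Expected cell-type proportions follow a linear-in-age trend on the proportion
scale, clipped to $(0.001, 0.999)$ and renormalised; realized counts are
multinomial. We put the trend on the proportion scale rather than the logit scale
deliberately: the truth bundle records a "true proportion slope" that downstream
least-squares recovery is compared against, and only the linear parametrisation
makes that number exact (slopes that sum to zero across types, as in the default
panel, are recovered without bias). `simulate_composition()` exposes this half of
the model alone, which is how the calibration studies avoid simulating gene
expression for hundreds of cohorts.

**Abnormal cells.** `generate_query()` draws query samples from the same
generative model (a fresh study with no batch factor) except that a fraction of
one type's cells carry an ectopic activation program: mean log-expression raised
by `shift_magnitude` on `n_shift_genes` (default 50) genes drawn from the *other*
types' marker panels. Two aspects of this choice matter. First, the program is
up-only: lowering genes a cell type barely expresses changes almost nothing on
the count scale, so signed shifts would make the planted magnitude a poor proxy
for the real displacement. Second, the program lives on marker genes because the
mapping stage only sees the highly-variable-gene space; a program on arbitrary
genes is largely invisible *in principle* to any embedding-based method — its
displacement has almost no projection on the reference principal components.
`shift_gene_pool = "random"` restores the arbitrary-gene variant for exactly that
kind of negative experiment.

**What the generator does not emulate.** No doublets or ambient RNA, no gene–gene
correlation beyond cell-type structure, no per-cell library-size covariates
beyond the Poisson cell-count draw, and batch effects are purely multiplicative
and study-wide. Passing tests therefore demonstrate that each stage recovers the
structure it is designed for under its stated assumptions — not that it is robust
to every artefact of real droplet data.

## Quality control and normalisation

Real studies set QC cut-offs per sample by inspecting metric distributions; that
is irreproducible, so `qc_filter()` takes explicit bounds (`qc_thresholds()`:
defaults min 200 detected genes, max 20% mitochondrial fraction, and whole-sample
removal below 200 surviving cells), with `adaptive_qc_thresholds()` offering a
documented median ± 3 MAD per-sample alternative on the log scale. Each removed
cell is assigned one reason in a fixed precedence order, so reasons partition the
removed set and reports are auditable. Normalisation is total-count scaling to
10,000 (the standard factor) followed by `log1p`; the zero pattern is preserved
and a zero-total cell is an error directing the user to QC first.

## Reference embedding

`consensus_hvg()` ranks genes per sample by the variance-to-mean ratio of
de-logged normalized expression and keeps the top 3,000 (desk-scale runs use
smaller lists), then ranks genes by how many samples' lists contain them, with
ties broken by higher overall mean expression and then gene id. The de-logged
scale matters: on log values the ratio is dominated by sampling noise in
low-expression genes, and genes expressed bimodally across cell types — exactly
the ones an embedding needs — are not reliably selected.

`scale_and_pca()` standardises each gene, clips scaled values at ±10 (guarding
the decomposition against single outlier cells), and takes the top 30 components
by SVD. The returned model freezes the gene list, scaling statistics, and
loadings, which is what makes later query projection a deterministic transform.

`batch_correct()` is a deliberately simplified stand-in for anchor-based
integration, behind a pluggable surface: mutual nearest neighbours between each
incoming study and the already-merged cells define pair vectors, which are
propagated to every cell by a Gaussian kernel over distance to the pair anchors.
The kernel is smoothed over a wide anchor neighbourhood (ten times `k_mnn`) with
bandwidth set to the median distance within that neighbourhood, and weights are
stabilised so distant cells still receive their local anchor average; a narrow,
unstabilised kernel makes the correction field jumpy enough to scramble
within-study neighbourhoods, violating the contract the tests enforce (≥ 80%
neighbourhood preservation under a constant offset, ≥ 90% centroid-gap removal).
Like every mutual-nearest-neighbour method it assumes the batch displacement is
approximately orthogonal to the biological manifold; the tests construct their
oracle inputs in that regime, and an isotropic full-rank cloud with an in-plane
offset is documented as out of reach rather than worked around.

Clustering builds an unweighted kNN graph (k = 20 by default; the graph, not the
weighting, is what the procedure specifies) and runs Louvain modularity
optimisation under a fixed seed. Cluster markers are one-vs-rest Wilcoxon
rank-sum tests on normalized expression with the conventional log fold change
$\ln\!\big(({\rm mean}\,{\rm expm1}(x)+1)/({\rm mean}\,{\rm expm1}(y)+1)\big)$
and Benjamini–Hochberg adjustment within cluster. Cluster-to-type annotation is
by majority true label on synthetic data (`annotate_clusters()`); manual
biological annotation is out of scope.

## Composition trends

`trend_test()` regresses each type's per-sample proportion on donor age with the
study as a categorical covariate. The printed form of this model in the
literature has no intercept and a single "project" term; we fit the identifiable
standard reading — intercept plus study dummies, reference level the first study
alphabetically — and report the two-sided t-test on the age coefficient as the
overall p-value (an F-test would answer a different question: whether anything,
including study, explains the proportions). Per study with at least three aged
samples a Spearman correlation is reported, with an optional Fisher combination.
Proportions are analysed untransformed, as the model is stated on percentages; a
logit option exists for robustness checks. A perfectly constant proportion is
reported as slope 0 with p = 1 rather than the 0/0 t-statistic. Formal
compositional (simplex) modelling is a non-goal.

## Age-gene screen

`pseudobulk()` averages expression per (sample, cell type) — batch-corrected
values by default, which at gene level come from limma's linear-model batch
removal (`correct_expression()`), since the MNN correction lives in PC space.
Eligibility follows the stated filters: a type needs at least 20 samples each
contributing at least 20 cells (we read "at least 20 cells" per sample, so an
entry only exists where that sample has 20+ cells of the type;
`per_sample = FALSE` switches to the total-count reading), and a gene must be
detected in strictly more than 10% of the type's cells. `age_correlation()`
computes Pearson r against donor age with two-sided p from the t-distribution on
$n-2$ degrees of freedom — the standard test at these sample sizes; a permutation
mode is unnecessary above a handful of samples — and retains rows with p < 0.01.
`ora_enrichment()` is a local hypergeometric over-representation test against
user-supplied GMT collections with BH adjustment (threshold 0.01); it replaces a
hosted enrichment service, whose databases are unpinned external resources.

## The age clock

`fit_clock()` fits one elastic-net regression per eligible cell type, age on
that type's age-related pseudobulk genes, with `alpha = 0.5` by default (neither
the mixing parameter nor the penalty grid is fixed by convention; 0.5 weights
sparsity and shrinkage equally and is tunable). The penalty path is 100
log-spaced values spanning four decades below the smallest all-zero penalty, and
the penalty is chosen by minimum cross-validated MSE (1-SE rule available).
Folds are assigned at the *sample* level from one seed and shared by every cell
type, so no fold ever mixes a sample's cell types between train and test. The
final coefficients are refit tightly at the selected penalty, which is what lets
the test suite verify the elastic-net stationarity conditions directly.
Features are standardised internally and the statistics stored in the model.

`predict_age()` predicts per cell type and takes the median across types (mean
of the two central values for even counts), per sample; negative predictions are
reported as-is and flagged. With a `mapping_gate`, pseudobulk is recomputed from
confidently mapped cells only before predicting — the intended use on disease
samples. `evaluate_clock()` runs sample-level 10-fold cross-validation of the
*whole* procedure, re-running the age-gene screen inside each training fold so
feature selection never sees test samples; eligibility decisions are kept from
the full table, since eligibility is a property of the cohort design rather than
of a fold. It reports the out-of-fold Pearson correlation and median absolute
error in years.

## Reference mapping and the confidence gate

`project_query()` matches query genes to the frozen model by id, scales with the
reference statistics (clip ±10), imputes genes missing from the query at the
reference mean (scaled value 0), errors below 50% feature overlap, and projects
with the reference loadings. Mapping is a frozen transform — the reference is
immutable and the mapping deterministic; a joint re-integration round is noted
as out of scope.

`transfer_labels()` gives each query cell the modal type among its 30 nearest
reference cells, ties broken by larger summed inverse distance and then
lexicographically. `confidence_scores()` computes $s_i = 1/(\bar d_i +
\varepsilon)$ from the mean of the 30 neighbour distances ($\varepsilon =
10^{-12}$ guards exact duplicates; the median is a config switch) and min–max
normalises to $[0,1]$ within the query dataset. `gate_confident()` fits a
two-component Gaussian mixture to the scores by EM (k-means initialisation under
a fixed seed, variance floor $10^{-8}$, convergence at $10^{-8}$ log-likelihood
improvement or 500 iterations); cells with posterior ≥ 0.5 for the *higher-mean*
component are confident — low scores mean "phenotypically unlike anything in the
healthy reference", the operational definition of a candidate diseased cell. A
degenerate all-equal input returns all cells confident with the model flagged.

`disease_de()` compares query and reference cells of one type by Wilcoxon
rank-sum per gene on normalized expression, with the same log-fold-change
convention as the cluster markers and significance at p < 0.05 and |logFC| > 0.5
(the conventional thresholds for this comparison); BH-adjusted p-values are
reported alongside.

## Numerical choices and degenerate inputs

Determinism is a contract: every stochastic step (generator, Louvain, fold
assignment, EM initialisation, truncated SVD) takes or derives a seed, and the
suite asserts byte-identical reruns. Degenerate inputs are handled explicitly:
empty datasets are valid, thresholds removing all cells warn rather than error,
all-equal confidence scores gate everything confident with a flag, zero-variance
genes are scaled to zero (PCA) or skipped with a flag (correlation screen), and
identical ages are a design error.

## Problem sizes

The shipped analyses and tests run on cohorts of 24 samples × 3 studies × ~250
cells × 400 genes for the atlas and mapping stages, 40 samples for the age-gene
screen, and 60 samples for the clock — sizes chosen so the full suite and the
analysis scripts complete in minutes on one CPU while leaving every planted
effect comfortably detectable at the stated thresholds.

## Known limitations

The batch correction is a simplified MNN stand-in, not anchor-based integration;
its guarantees are the tested contracts above, under the orthogonality
assumption. Gene-level corrected values come from a linear batch model. The
generator's independence assumptions (above) mean real-data robustness is not
demonstrated here. Real-data headline figures from atlas-scale cohorts — hundreds
of samples, dozens of cell types, clock accuracy on human donors — depend on data
this package deliberately does not ship and are not reproduced.
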