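# Shared desk-scale fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 3 studies x 8 samples reference cohort with the default bone-marrow-like
# panel, processed up to the PCA embedding.
atlas_fixture <- function() fixture("atlas", function() {
  cfg <- example_cohort_config(n_studies = 3, samples_per_study = 8,
                               n_genes = 400, mean_cells_per_sample = 250,
                               seed = 41)
  gen <- generate_reference(cfg)
  qc <- qc_filter(gen$dataset,
                  qc_thresholds(min_genes = 50, min_cells_per_sample = 100))
  ds <- normalize_total(qc$dataset)
  hvg <- consensus_hvg(ds, per_sample_n = 150, consensus_n = 150)
  em <- scale_and_pca(ds, hvg, n_components = 30)
  ref_labels <- gen$truth$true_labels[rownames(em$reference_embedding)]
  list(cfg = cfg, gen = gen, ds = ds, hvg = hvg, em = em,
       ref_labels = ref_labels)
})

# Query with half the plasma cells carrying a strong 50-gene ectopic program.
query_fixture <- function() fixture("query", function() {
  fx <- atlas_fixture()
  q <- generate_query(fx$cfg, n_samples = 6, abnormal_fraction = 0.5,
                      shift_magnitude = 5, shifted_cell_type = "Plasma",
                      seed = 99)
  q$dataset <- normalize_total(q$dataset)
  q
})

# 40-sample cohort (2 studies x 20) for the age-gene screen.
agegene_fixture <- function() fixture("agegene", function() {
  cfg <- example_cohort_config(n_studies = 2, samples_per_study = 20,
                               n_genes = 400, mean_cells_per_sample = 250,
                               seed = 21)
  gen <- generate_reference(cfg)
  ds <- normalize_total(qc_filter(gen$dataset,
    qc_thresholds(min_genes = 50, min_cells_per_sample = 100))$dataset)
  ds <- correct_expression(ds)
  pb <- pseudobulk(ds)
  list(cfg = cfg, gen = gen, ds = ds, pb = pb)
})

# 60-sample cohort (3 studies x 20) for the clock.
clock_fixture <- function() fixture("clock", function() {
  cfg <- example_cohort_config(n_studies = 3, samples_per_study = 20,
                               n_genes = 400, mean_cells_per_sample = 250,
                               seed = 31)
  gen <- generate_reference(cfg)
  ds <- normalize_total(qc_filter(gen$dataset,
    qc_thresholds(min_genes = 50, min_cells_per_sample = 100))$dataset)
  ds <- correct_expression(ds)
  pb <- pseudobulk(ds)
  list(cfg = cfg, gen = gen, ds = ds, pb = pb,
       ages = gen$truth$sample_ages)
})

# Mann-Whitney AUROC of `score` for separating `positive`.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (no ties assumed).
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- n * (n + m + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Construct a dataset whose per-sample normalized values are fully under the
# test's control.
ds_from_norm <- function(norm_list, gene_ids) {
  samples <- names(norm_list)
  mats <- lapply(norm_list, function(m) methods::as(Matrix::Matrix(
    m, sparse = TRUE), "CsparseMatrix"))
  norm <- do.call(cbind, mats)
  cells <- data.frame(
    cell_id = sprintf("C%03d", seq_len(ncol(norm))),
    sample_id = rep(samples, vapply(norm_list, ncol, 0L)),
    study_id = "ST1")
  counts <- methods::as(Matrix::Matrix(round(expm1(as.matrix(norm))),
                                       sparse = TRUE), "CsparseMatrix")
  ds <- cell_dataset(counts, cells,
                     data.frame(gene_id = gene_ids, symbol = gene_ids),
                     data.frame(sample_id = samples, study_id = "ST1"))
  ds$normalized <- norm
  dimnames(ds$normalized) <- dimnames(ds$counts)
  ds
}

# A minimal hand-built pseudobulk table over one or more cell types.
toy_pb <- function(values_by_type, n_cells = 30) {
  types <- names(values_by_type)
  vals <- do.call(rbind, unname(values_by_type))
  et <- do.call(rbind, lapply(types, function(tp)
    data.frame(sample_id = rownames(values_by_type[[tp]]), cell_type = tp,
               n_cells = n_cells, stringsAsFactors = FALSE)))
  structure(list(values = vals, entry_table = et,
                 eligible_cell_types = types,
                 eligible_genes = lapply(setNames(nm = types), function(tp)
                   colnames(vals)),
                 params = list(min_cells = 1, min_samples = 1,
                               detection_fraction = 0, per_sample = TRUE,
                               values = "normalized")),
            class = "PseudobulkTable")
}

toy_agt <- function(pb) {
  do.call(rbind, lapply(pb$eligible_cell_types, function(tp)
    data.frame(cell_type = tp, gene_id = colnames(pb$values),
               pearson_r = 0.9, p = 1e-6, direction = "up",
               stringsAsFactors = FALSE)))
}
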