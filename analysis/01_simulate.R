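#!/usr/bin/env Rscript
# Simulate the study cohorts: a multi-study healthy bone-marrow-like
# reference and a disease-like query in which half of the plasma cells carry
# an ectopic 50-gene activation program. Writes datasets and planted truth
# under results/data/.

suppressMessages(library(marrowatlas))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- example_cohort_config(n_studies = 3, samples_per_study = 8,
                             n_genes = 400, mean_cells_per_sample = 250,
                             seed = 20260929)
ref <- generate_reference(cfg)
cat("Reference cohort:\n")
print(ref$dataset)
cat(sprintf("  ages %0.f-%0.f years, %d planted age genes, trends: %s\n",
            min(ref$truth$sample_ages), max(ref$truth$sample_ages),
            nrow(ref$truth$age_genes),
            paste(sprintf("%s %+0.4f/yr", names(ref$truth$trend_cell_types),
                          ref$truth$trend_cell_types), collapse = ", ")))

qry <- generate_query(cfg, n_samples = 6, abnormal_fraction = 0.5,
                      shift_magnitude = 5, shifted_cell_type = "Plasma",
                      seed = 7341)
cat("Query cohort:\n")
print(qry$dataset)
cat(sprintf("  %d abnormal plasma cells (ectopic +5 log-units on %d genes)\n",
            length(qry$truth$abnormal_cells), nrow(qry$truth$shift_genes)))

write_dataset(ref$dataset, "results/data/reference")
write_truth(ref$truth, "results/data/reference_truth")
write_dataset(qry$dataset, "results/data/query")
write_truth(qry$truth, "results/data/query_truth")
saveRDS(cfg, "results/data/cohort_config.rds")
cat("written: results/data/{reference,query}[_truth]\n")
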