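#!/usr/bin/env Rscript
# Quality control and total-count normalisation of the simulated cohorts.
# Cells failing per-cell bounds are removed, then samples retaining fewer
# than the floor; surviving cells are log-normalised to 10,000 counts.

suppressMessages(library(marrowatlas))

thr <- qc_thresholds(min_genes = 50, max_mito_fraction = 0.2,
                     min_cells_per_sample = 100)

for (side in c("reference", "query")) {
  ds <- read_dataset(file.path("results/data", side))
  res <- qc_filter(ds, thr)
  kept <- ncol(res$dataset$counts)
  cat(sprintf("%s: %d/%d cells pass QC; %d/%d samples retained\n", side,
              kept, ncol(ds$counts), nrow(res$dataset$sample_table),
              nrow(ds$sample_table)))
  if (nrow(res$report$cell_reasons)) {
    tab <- table(res$report$cell_reasons$reason)
    cat("  removal reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  norm <- normalize_total(res$dataset, scale_factor = 1e4)
  write_dataset(norm, file.path("results/data", paste0(side, "_qc")))
  write.table(res$report$sample_summary,
              file.path("results", paste0("qc_", side, "_samples.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("written: results/data/{reference,query}_qc, results/qc_*_samples.tsv\n")
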