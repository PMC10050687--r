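test_that("pseudobulk means equal brute-force per-group averages", {
  fx <- atlas_fixture()
  ds <- subset_cells(fx$ds, seq_len(50), drop_empty_samples = TRUE)
  pb <- pseudobulk(ds, values = "normalized", min_cells = 1, min_samples = 1)
  expr <- as.matrix(ds$normalized)
  for (i in seq_len(nrow(pb$entry_table))) {
    et <- pb$entry_table[i, ]
    sel <- ds$cell_table$sample_id == et$sample_id &
      ds$cell_table$label == et$cell_type
    expect_equal(unname(pb$values[i, ]),
                 unname(rowMeans(expr[, sel, drop = FALSE])))
    expect_identical(pb$entry_table$n_cells[i], sum(sel))
  }
})

test_that("eligibility filters follow the stated counts and strict fraction", {
  # one cell type across 25 samples; another in only 19
  set.seed(16)
  n_cells <- 25 * 22 + 19 * 25
  sample_id <- c(rep(sprintf("P%02d", 1:25), each = 22),
                 rep(sprintf("Q%02d", 1:19), each = 25))
  label <- c(rep("Common", 25 * 22), rep("Rare", 19 * 25))
  counts <- matrix(rpois(10 * n_cells, 3), 10, n_cells)
  # gene g10 detected in exactly 10% of Common cells (boundary)
  common_cols <- which(label == "Common")
  counts[10, ] <- 0
  counts[10, common_cols[seq_len(0.10 * length(common_cols))]] <- 1
  ds <- cell_dataset(counts,
                     data.frame(cell_id = sprintf("c%04d", 1:n_cells),
                                sample_id = sample_id, study_id = "A",
                                label = label),
                     data.frame(gene_id = sprintf("g%02d", 1:10),
                                symbol = sprintf("g%02d", 1:10)),
                     data.frame(sample_id = unique(sample_id),
                                study_id = "A"))
  ds <- normalize_total(ds)
  pb <- pseudobulk(ds, values = "normalized", min_cells = 20,
                   min_samples = 20)
  expect_identical(pb$eligible_cell_types, "Common")   # 19 samples -> out
  expect_false("g10" %in% pb$eligible_genes$Common)    # exactly 10% -> out
  counts[10, common_cols[1:(0.10 * length(common_cols) + 5)]] <- 1
  ds2 <- normalize_total(cell_dataset(counts, ds$cell_table, ds$gene_table,
                                      ds$sample_table))
  pb2 <- pseudobulk(ds2, values = "normalized", min_cells = 20,
                    min_samples = 20)
  expect_true("g10" %in% pb2$eligible_genes$Common)
})

test_that("eligibility is order-independent", {
  fx <- agegene_fixture()
  pb <- fx$pb
  # gene filter restricted to eligible types equals filtering types first
  for (tp in pb$eligible_cell_types) {
    cells <- fx$ds$cell_table$label == tp
    det <- Matrix::rowSums(fx$ds$counts[, cells, drop = FALSE] > 0) /
      sum(cells)
    expect_setequal(pb$eligible_genes[[tp]],
                    fx$ds$gene_table$gene_id[det > 0.1])
  }
})

test_that("Pearson screen matches the closed-form t oracle and cor.test", {
  # fixed 6-point vectors
  age <- c(22, 31, 40, 52, 63, 78)
  expr <- c(1.8, 2.4, 2.1, 3.0, 3.4, 3.9)
  ct <- cor.test(expr, age)               # independent oracle
  pb <- structure(list(
    values = matrix(rep(expr, 2), 6, 2,
                    dimnames = list(NULL, c("gA", "gB"))),
    entry_table = data.frame(sample_id = sprintf("S%d", 1:6),
                             cell_type = "T", n_cells = 30),
    eligible_cell_types = "T",
    eligible_genes = list(T = c("gA", "gB")),
    params = list(min_cells = 20, min_samples = 3, per_sample = TRUE,
                  detection_fraction = 0.1, values = "normalized")),
    class = "PseudobulkTable")
  pb$values[, 2] <- rev(expr)
  ages <- setNames(age, sprintf("S%d", 1:6))
  agt <- age_correlation(pb, ages, p_threshold = 1)
  got <- agt[agt$gene_id == "gA", ]
  expect_equal(got$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  # perfect linearity -> r = 1, vanishing p
  pb$values[, 2] <- 2 + 0.05 * age
  agt2 <- age_correlation(pb, ages, p_threshold = 1)
  expect_equal(agt2$pearson_r[agt2$gene_id == "gB"], 1, tolerance = 1e-9)
  expect_lt(agt2$p[agt2$gene_id == "gB"], 1e-10)
  # zero-variance gene skipped and flagged
  pb$values[, 2] <- 5
  agt3 <- age_correlation(pb, ages, p_threshold = 1)
  expect_false("gB" %in% agt3$gene_id)
  expect_identical(attr(agt3, "skipped")$gene_id, "gB")
})

test_that("null genes are retained at about the nominal 1% rate", {
  set.seed(17)
  n_genes <- 12000; n_samp <- 40
  vals <- matrix(rnorm(n_samp * n_genes), n_samp, n_genes,
                 dimnames = list(NULL, sprintf("g%05d", seq_len(n_genes))))
  pb <- structure(list(
    values = vals,
    entry_table = data.frame(sample_id = sprintf("S%02d", 1:n_samp),
                             cell_type = "T", n_cells = 50),
    eligible_cell_types = "T",
    eligible_genes = list(T = colnames(vals)),
    params = list(min_cells = 20, min_samples = 3, per_sample = TRUE,
                  detection_fraction = 0.1, values = "normalized")),
    class = "PseudobulkTable")
  ages <- setNames(runif(n_samp, 2, 84), sprintf("S%02d", 1:n_samp))
  agt <- age_correlation(pb, ages, p_threshold = 0.01)
  rate <- nrow(agt) / n_genes
  mc <- 3 * sqrt(0.01 * 0.99 / n_genes)
  expect_lt(abs(rate - 0.01), mc + 1e-3)
})

test_that("planted age genes are found; sharing counts are exact tallies", {
  fx <- agegene_fixture()
  agt <- age_correlation(fx$pb, fx$gen$truth$sample_ages)
  hits <- paste(agt$cell_type, agt$gene_id)
  planted <- paste(fx$gen$truth$age_genes$cell_type,
                   fx$gen$truth$age_genes$gene_id)
  expect_gte(mean(planted %in% hits), 0.9)
  sh <- shared_gene_summary(agt)
  expect_identical(sum(sh$n_cell_types), nrow(agt))
  tally <- table(agt$gene_id)
  for (g in head(sh$gene_id, 10))
    expect_identical(sh$n_cell_types[sh$gene_id == g], unname(tally[[g]]))
  one <- names(tally)[tally == 1][1]
  if (!is.na(one))
    expect_identical(sh$n_cell_types[sh$gene_id == one], 1L)
})

test_that("hypergeometric ORA matches direct tail summation", {
  universe <- sprintf("u%03d", 1:100)
  hits <- universe[1:10]
  sets <- list(hit5 = c(universe[6:10], universe[51:55]),
               disjoint = universe[61:70],
               whole = universe)
  res <- ora_enrichment(hits, sets, universe, adj_threshold = 0.01)
  # direct tail sum for overlap >= 5 with K = 10, N = 100, n = 10
  p_direct <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k), 0)) / choose(100, 10)
  expect_equal(res$p[res$set == "hit5"], p_direct, tolerance = 1e-12)
  expect_equal(res$p[res$set == "disjoint"], 1)
  expect_equal(res$p[res$set == "whole"], 1)
  expect_true(all(diff(res$p_adj[order(res$p)]) >= -1e-12))
  expect_error(ora_enrichment(c(hits, "zzz"), sets, universe), "zzz")
})
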