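test_that("projection is self-consistent, handles missing genes, is linear", {
  fx <- atlas_fixture()
  em <- fx$em
  # a reference cell pushed through project_query lands on its own row
  sub <- subset_cells(fx$ds, seq_len(20), drop_empty_samples = TRUE)
  qe <- project_query(em, sub)
  expect_lt(max(abs(qe - em$reference_embedding[seq_len(20), ])), 1e-6)
  # all-zero expression projects the (-mean/sd) vector, clipped
  z <- sub
  z$normalized <- z$normalized * 0
  qz <- project_query(em, z)
  v <- pmin(pmax(-em$scale_means / em$scale_sds, -em$clip), em$clip)
  expect_lt(max(abs(qz[1, ] - drop(v %*% em$pca_loadings))), 1e-8)
  # linearity of the unclipped transform on constructed vectors
  hv <- em$hvg_genes
  f <- function(x) drop(((x - em$scale_means) / em$scale_sds) %*%
                          em$pca_loadings)
  set.seed(22)
  x1 <- runif(length(hv)); x2 <- runif(length(hv))
  centre <- f(0 * x1)
  expect_equal(f(2 * x1 + 3 * x2) - centre,
               2 * (f(x1) - centre) + 3 * (f(x2) - centre),
               tolerance = 1e-10)
  # insufficient overlap errors
  few <- subset_cells(fx$ds, seq_len(5), drop_empty_samples = TRUE)
  keep_genes <- seq_len(nrow(few$counts))[1:60]
  few$counts <- few$counts[keep_genes, ]
  few$normalized <- few$normalized[keep_genes, ]
  few$gene_table <- few$gene_table[keep_genes, ]
  expect_error(project_query(em, few), "feature overlap")
})

test_that("label transfer tallies neighbours with the documented tie rules", {
  # reference: 30 cells, constructed distances
  ref <- matrix(0, 30, 2)
  ref[, 1] <- seq_len(30)
  rownames(ref) <- sprintf("r%02d", 1:30)
  qry <- matrix(c(0, 0), 1, 2)
  # unanimity
  tr <- transfer_labels(ref, rep("A", 30), qry, k = 30)
  expect_identical(unname(tr$labels), "A")
  # 16/14 majority
  lab <- c(rep("A", 16), rep("B", 14))
  tr2 <- transfer_labels(ref, lab, qry, k = 30)
  expect_identical(unname(tr2$labels), "A")
  # 15/15 tie: B strictly closer wins by summed inverse distance
  lab3 <- c(rep("B", 15), rep("A", 15))
  tr3 <- transfer_labels(ref, lab3, qry, k = 30)
  expect_identical(unname(tr3$labels), "B")
  # equidistant tie falls back to lexicographic order
  ref4 <- matrix(rep(c(1, -1), each = 2), 2, 2)
  rownames(ref4) <- c("r1", "r2")
  tr4 <- transfer_labels(ref4, c("Z", "Q"), qry, k = 2)
  expect_identical(unname(tr4$labels), "Q")
})

test_that("confidence scores follow the inverse-mean-distance definition", {
  d <- matrix(c(1, 2, 4), 3, 5)   # mean distances 1, 2, 4
  cs <- confidence_scores(d, epsilon = 0)
  expect_equal(cs$raw, c(1, 0.5, 0.25))
  expect_equal(cs$confidence, c(1, 1 / 3, 0))
  # endpoints
  expect_equal(cs$confidence[which.min(rowMeans(d))], 1)
  expect_equal(cs$confidence[which.max(rowMeans(d))], 0)
  # invariant to global rescaling of distances
  cs2 <- confidence_scores(37.5 * d, epsilon = 0)
  expect_equal(cs2$confidence, cs$confidence)
  # monotone decreasing in mean distance
  set.seed(23)
  dd <- matrix(rexp(300), 100, 3)
  cc <- confidence_scores(dd)
  o <- order(rowMeans(dd))
  expect_true(all(diff(cc$confidence[o]) <= 1e-12))
  expect_warning(confidence_scores(matrix(1, 4, 2)), "equal")
})

test_that("the mixture gate recovers separated and simulated components", {
  # point masses at 0.1 and 0.9
  x <- rep(c(0.1, 0.9), each = 50)
  g <- gate_confident(x, seed = 1)
  expect_equal(sort(g$means), c(0.1, 0.9), tolerance = 1e-6)
  expect_identical(g$confident, x == 0.9)
  # simulated normals, recovery within 0.02
  set.seed(24)
  y <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.8, 0.05))
  g2 <- gate_confident(y, seed = 2)
  expect_lt(abs(sort(g2$means)[1] - 0.3), 0.02)
  expect_lt(abs(sort(g2$means)[2] - 0.8), 0.02)
  expect_identical(g2$confident_component, which.max(g2$means))
  # EM log-likelihood is non-decreasing
  expect_true(all(diff(g2$loglik) >= -1e-8))
  # cross-check against an independent mixture fitter
  withr::local_package("mclust")
  mc <- mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(g2$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  # degenerate input
  gd <- gate_confident(rep(0.5, 20), seed = 1)
  expect_true(gd$degenerate)
  expect_true(all(gd$confident))
})

test_that("query mapping separates planted abnormal cells", {
  fx <- atlas_fixture()
  q <- query_fixture()
  mp <- map_query(fx$em, fx$ref_labels, q$dataset, k = 30, seed = 7)
  is_ab <- mp$cells$cell_id %in% q$truth$abnormal_cells
  truth_lab <- q$truth$true_labels[mp$cells$cell_id]
  # held-out normal cells relabelled correctly
  expect_gte(mean(mp$cells$transferred_label[!is_ab] == truth_lab[!is_ab]),
             0.95)
  # low confidence discriminates the abnormal program
  expect_gte(auroc(-mp$cells$confidence, is_ab), 0.9)
  # the non-confident gate recalls most abnormal cells
  expect_gte(mean(!mp$cells$confident[is_ab]), 0.8)
  # the confident component is the higher-mean one by construction
  expect_gte(mp$gate$means[mp$gate$confident_component],
             max(mp$gate$means) - 1e-12)
  expect_identical(ncol(mp$neighbor_ids), 30L)
})

test_that("a null shift leaves flagged cells indistinguishable", {
  fx <- atlas_fixture()
  q0 <- generate_query(fx$cfg, n_samples = 4, abnormal_fraction = 0.5,
                       shift_magnitude = 0, shifted_cell_type = "Plasma",
                       seed = 55)
  # zero magnitude plants no displacement; flag a random plasma subset
  qd <- normalize_total(q0$dataset)
  mp <- map_query(fx$em, fx$ref_labels, qd, seed = 3)
  set.seed(26)
  is_plasma <- q0$truth$true_labels[mp$cells$cell_id] == "Plasma"
  conf_p <- mp$cells$confidence[is_plasma]
  fake_ab <- seq_along(conf_p) %in% sample(seq_along(conf_p),
                                           length(conf_p) %/% 2)
  a <- auroc(-conf_p, fake_ab)
  n1 <- sum(fake_ab); n0 <- sum(!fake_ab)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))   # null AUROC Monte-Carlo SE
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("disease DE is exact on toy vectors and finds the planted program", {
  # identical groups: nothing significant
  fx <- atlas_fixture()
  plasma <- subset_cells(fx$ds, fx$ds$cell_table$label == "Plasma",
                         drop_empty_samples = TRUE)
  de0 <- disease_de(plasma, plasma, "Plasma")
  expect_false(any(de0$significant))
  # printed 5-vs-5 vectors: exact enumeration oracle
  x <- c(2.31, 0.84, 3.92, 1.05, 2.77)
  y <- c(0.12, 1.41, 0.55, 0.98, 0.20)
  mk <- function(v, ids) {
    cell_dataset(matrix(round(expm1(v)), 1),
                 data.frame(cell_id = ids, sample_id = "S", study_id = "A",
                            label = "P"),
                 data.frame(gene_id = "g1", symbol = "g1"),
                 data.frame(sample_id = "S", study_id = "A"))
  }
  dq <- mk(x, sprintf("q%d", 1:5)); dr <- mk(y, sprintf("r%d", 1:5))
  dq$normalized <- methods::as(Matrix::Matrix(matrix(x, 1), sparse = TRUE),
                               "CsparseMatrix")
  dimnames(dq$normalized) <- dimnames(dq$counts)
  dr$normalized <- methods::as(Matrix::Matrix(matrix(y, 1), sparse = TRUE),
                               "CsparseMatrix")
  dimnames(dr$normalized) <- dimnames(dr$counts)
  de <- disease_de(dq, dr, "P")
  expect_equal(de$p, exact_ranksum_p(x, y), tolerance = 1e-12)
  # planted 50-gene shift: most shifted genes pass the default thresholds
  q <- query_fixture()
  de2 <- disease_de(q$dataset, fx$ds, "Plasma")
  sig <- de2$gene_id[de2$significant]
  expect_gte(mean(q$truth$shift_genes$gene_id %in% sig), 0.8)
  # error when the type is missing on one side
  expect_error(disease_de(q$dataset, fx$ds, "Nothere"), "absent")
})
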