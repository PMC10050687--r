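test_that("consensus of a single sample is that sample's own top list", {
  fx <- atlas_fixture()
  one <- subset_cells(fx$ds,
                      fx$ds$cell_table$sample_id ==
                        fx$ds$cell_table$sample_id[1],
                      drop_empty_samples = TRUE)
  top <- consensus_hvg(one, per_sample_n = 50, consensus_n = 50)
  # oracle: rank this sample's genes by the documented dispersion statistic
  m <- expm1(as.matrix(one$normalized))
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  own <- one$gene_table$gene_id[
    order(-disp, -mu, one$gene_table$gene_id)][1:50]
  expect_setequal(top, own)
})

test_that("consensus selection matches exhaustive frequency enumeration", {
  # 3 samples x 10 genes with constructed dispersions
  set.seed(8)
  gene_ids <- sprintf("g%02d", 1:10)
  mk <- function(sds) {
    m <- matrix(0, 10, 12)
    for (g in 1:10) m[g, ] <- abs(rnorm(12, mean = 1, sd = sds[g]))
    m
  }
  norm_list <- list(S1 = mk(c(5, 4, 3, 2, rep(0.05, 6))),
                    S2 = mk(c(0.05, 4, 3, 2, 5, rep(0.05, 5))),
                    S3 = mk(c(5, 4, 0.05, 2, 0.05, 3, rep(0.05, 4))))
  ds <- ds_from_norm(norm_list, gene_ids)
  got <- consensus_hvg(ds, per_sample_n = 4, consensus_n = 3)

  # independent oracle: recompute per-sample dispersion ranks, count list
  # membership, apply the documented tie rule
  freq <- setNames(integer(10), gene_ids)
  for (s in names(norm_list)) {
    m <- expm1(norm_list[[s]])
    disp <- apply(m, 1, var) / rowMeans(m)
    mean_ <- rowMeans(m)
    ord <- order(-disp, -mean_, gene_ids)
    freq[gene_ids[ord[1:4]]] <- freq[gene_ids[ord[1:4]]] + 1L
  }
  overall <- rowMeans(expm1(do.call(cbind, norm_list)))
  oracle <- gene_ids[order(-freq, -overall, gene_ids)][1:3]
  expect_identical(got, oracle)
  # genes appearing in every sample's list are always selected
  expect_true(all(names(freq)[freq == 3] %in% got))
})

test_that("scale_and_pca satisfies the SVD identities", {
  fx <- atlas_fixture()
  em <- fx$em
  # orthonormal loadings
  gram <- crossprod(em$pca_loadings)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-6)
  # non-increasing explained variance
  expect_true(all(diff(em$sdev) <= 1e-10))
  # reconstruction: embedding equals scaled matrix times loadings
  x <- t(as.matrix(fx$ds$normalized[em$hvg_genes, , drop = FALSE]))
  xs <- sweep(sweep(x, 2, em$scale_means), 2, em$scale_sds, "/")
  xs[xs > em$clip] <- em$clip; xs[xs < -em$clip] <- -em$clip
  expect_lt(max(abs(xs %*% em$pca_loadings - em$reference_embedding)), 1e-6)
  expect_error(scale_and_pca(fx$ds, fx$hvg, n_components = 1e6),
               "n_components")
})

test_that("rank-deficient data put no variance beyond the true rank", {
  set.seed(4)
  basis <- matrix(rnorm(40), 20, 2)
  scores <- matrix(rnorm(400), 200, 2)
  norm <- t(scores %*% t(basis))          # exactly rank 2, genes x cells
  norm <- norm - min(norm)
  ds <- ds_from_norm(list(S1 = norm), sprintf("g%02d", 1:20))
  em <- scale_and_pca(ds, ds$gene_table$gene_id, n_components = 10,
                      clip = 1e6)
  expect_lt(max(em$sdev[3:10]^2), 1e-8)
})

test_that("single-study batch correction is the identity", {
  set.seed(5)
  emb <- matrix(rnorm(600), 200, 3)
  expect_identical(batch_correct(emb, rep("A", 200)), emb)
})

test_that("a constant inter-study offset is removed almost entirely", {
  # biology on a low-dimensional structure (three clusters in the first two
  # coordinates), batch offset along a complementary direction — the regime
  # the mutual-nearest-neighbour assumption describes
  set.seed(6)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  mk <- function(n) {
    cl <- sample(1:3, n, TRUE)
    cbind(centers[cl, 1] + rnorm(n), centers[cl, 2] + rnorm(n),
          rnorm(n, sd = 0.3))
  }
  offset <- c(0, 0, 8)
  emb <- rbind(mk(200), sweep(mk(200), 2, offset, "+"))
  study <- rep(c("A", "B"), each = 200)
  corr <- batch_correct(emb, study)
  d_before <- sqrt(sum((colMeans(emb[1:200, ]) - colMeans(emb[201:400, ]))^2))
  d_after <- sqrt(sum((colMeans(corr[1:200, ]) - colMeans(corr[201:400, ]))^2))
  expect_lt(d_after, 0.1 * d_before)
  # within-study neighbourhoods survive the correction
  nn_before <- marrowatlas:::knn_search(emb[201:400, ], emb[201:400, ], 11)$idx
  nn_after <- marrowatlas:::knn_search(corr[201:400, ], corr[201:400, ], 11)$idx
  overlap <- mean(vapply(seq_len(200), function(i)
    length(intersect(nn_before[i, -1], nn_after[i, -1])) / 10, 0))
  expect_gte(overlap, 0.8)
})

test_that("correction improves study mixing on planted batch effects", {
  fx <- atlas_fixture()
  emb <- fx$em$reference_embedding
  study <- fx$ds$cell_table$study_id
  mixing <- function(e) {
    nn <- marrowatlas:::knn_search(e, e, 21)$idx
    mean(vapply(seq_len(nrow(e)), function(i)
      mean(study[nn[i, -1]] == study[i]), 0))
  }
  corr <- batch_correct(emb, study)
  expect_lt(mixing(corr), mixing(emb))
})

test_that("Louvain clustering recovers two planted blobs deterministically", {
  set.seed(9)
  emb <- rbind(matrix(rnorm(2000), 200, 10),
               matrix(rnorm(2000, mean = 20 / sqrt(10)), 200, 10))
  rownames(emb) <- sprintf("c%03d", 1:400)
  truth <- rep(1:2, each = 200)
  cl <- cluster_cells(emb, k = 30, seed = 2)
  expect_identical(length(unique(cl$assignments)), 2L)
  agree <- max(mean(cl$assignments == truth), mean(cl$assignments != truth))
  expect_gte(agree, 0.99)
  expect_gte(cl$modularity, 0)   # beats the all-in-one partition (Q = 0)
  cl2 <- cluster_cells(emb, k = 30, seed = 2)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(cluster_cells(emb, k = 400), "k must be smaller")
})

test_that("cluster markers: null gene, exact small-sample p, planted markers", {
  # identical values in and out of cluster -> p = 1, logFC = 0
  set.seed(10)
  norm <- rbind(rep(1.3, 12), matrix(abs(rnorm(36)), 3, 12))
  ds <- ds_from_norm(list(S1 = norm), sprintf("g%d", 1:4))
  asg <- setNames(rep(c(1L, 2L), each = 6), ds$cell_table$cell_id)
  mk <- cluster_markers(ds, asg)
  row1 <- mk[mk$cluster == 1 & mk$gene_id == "g1", ]
  expect_equal(row1$p, 1)
  expect_equal(row1$logFC, 0)

  # tiny two-group case equals exhaustive permutation enumeration
  x <- c(1.1, 3.4, 2.2, 5.1); y <- c(0.4, 0.9, 2.8, 1.7)
  norm2 <- rbind(c(x, y), matrix(1, 1, 8))
  ds2 <- ds_from_norm(list(S1 = norm2), c("gA", "gB"))
  asg2 <- setNames(rep(c(1L, 2L), each = 4), ds2$cell_table$cell_id)
  mk2 <- cluster_markers(ds2, asg2)
  expect_equal(mk2$p[mk2$cluster == 1 & mk2$gene_id == "gA"],
               exact_ranksum_p(x, y))

  # planted markers rank at the top for their own type's cluster
  fx <- atlas_fixture()
  keep <- seq_len(1500)
  ds3 <- subset_cells(fx$ds, keep, drop_empty_samples = TRUE)
  asg3 <- setNames(as.integer(factor(ds3$cell_table$label)),
                   ds3$cell_table$cell_id)
  mk3 <- cluster_markers(ds3, asg3)
  lev <- levels(factor(ds3$cell_table$label))
  for (ct in fx$cfg$cell_types) {
    cid <- match(ct$name, lev)
    tab <- mk3[mk3$cluster == cid, ]
    tab <- tab[order(tab$p, -tab$logFC), ]
    planted <- fx$gen$dataset$gene_table$gene_id[ct$marker_genes]
    expect_gte(sum(head(tab$gene_id, 10) %in% planted), 10)
  }
  expect_true(all(mk3$p >= 0 & mk3$p <= 1))
  # BH adjustment is monotone in raw p within each cluster
  for (cid in unique(mk3$cluster)) {
    sub <- mk3[mk3$cluster == cid, ]
    o <- order(sub$p)
    expect_true(all(diff(sub$p_adj[o]) >= -1e-12))
  }
})

test_that("clusters align with true cell types (ARI >= 0.8)", {
  fx <- atlas_fixture()
  corr <- batch_correct(fx$em$reference_embedding,
                        fx$ds$cell_table$study_id)
  cl <- cluster_cells(corr, k = 20, seed = 3)
  ari <- mclust::adjustedRandIndex(cl$assignments,
                                   fx$ref_labels[names(cl$assignments)])
  expect_gte(ari, 0.8)
  ann <- annotate_clusters(cl$assignments, fx$ref_labels)
  expect_true(all(ann %in% unique(fx$ref_labels)))
})
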