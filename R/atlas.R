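#' Consensus highly-variable genes across samples
#'
#' Per sample, genes are ranked by a dispersion statistic — the
#' variance-to-mean ratio of de-logged normalized expression (`expm1`), on
#' which scale genes expressed bimodally across cell types stand out — and
#' the top `per_sample_n` taken; the per-sample lists are then merged and
#' genes ranked by how many samples' lists contain them. Ties are broken by
#' higher overall mean (de-logged) expression, then lexicographic gene id.
#'
#' @param ds a normalized `CellDataset`.
#' @param per_sample_n genes kept per sample (default 3000).
#' @param consensus_n genes returned (default 3000).
#' @return character vector of gene ids, most-shared first.
#' @export
consensus_hvg <- function(ds, per_sample_n = 3000, consensus_n = 3000) {
  if (is.null(ds$normalized)) stop("run normalize_total first", call. = FALSE)
  genes <- ds$gene_table$gene_id
  if (length(genes) < consensus_n) {
    warning("fewer genes (", length(genes), ") than consensus_n (",
            consensus_n, "); returning all genes")
  }
  samples <- unique(ds$cell_table$sample_id)
  expr <- ds$normalized
  expr@x <- expm1(expr@x)
  freq <- stats::setNames(integer(length(genes)), genes)
  for (s in samples) {
    m <- expr[, ds$cell_table$sample_id == s, drop = FALSE]
    st <- sparse_row_stats(m)
    disp <- ifelse(st$mean > 0, st$var / st$mean, 0)
    ord <- order(-disp, -st$mean, genes)
    top <- genes[ord[seq_len(min(per_sample_n, length(genes)))]]
    freq[top] <- freq[top] + 1L
  }
  overall_mean <- Matrix::rowMeans(expr)
  ord <- order(-freq, -overall_mean, genes)
  genes[ord[seq_len(min(consensus_n, length(genes)))]]
}

#' Scale expression and compute the reference PCA
#'
#' Standardises each highly-variable gene (centre, unit variance, values
#' clipped at +/- `clip`) and decomposes the scaled cells x genes matrix by
#' SVD. The returned `EmbeddingModel` freezes everything needed to project
#' query cells later: the gene list, scaling statistics, and loadings.
#'
#' @param ds a normalized `CellDataset`.
#' @param hvg character vector of gene ids (subset of `ds` genes).
#' @param n_components PCs to keep (default 30).
#' @param clip cap on absolute scaled values (default 10).
#' @return an `EmbeddingModel`: `hvg_genes`, `scale_means`, `scale_sds`,
#'   `clip`, `pca_loadings` (genes x components, orthonormal columns),
#'   `sdev`, `reference_embedding` (cells x components), `neighbor_k`.
#' @export
scale_and_pca <- function(ds, hvg, n_components = 30, clip = 10) {
  if (is.null(ds$normalized)) stop("run normalize_total first", call. = FALSE)
  if (!all(hvg %in% ds$gene_table$gene_id))
    stop("hvg contains genes absent from the dataset", call. = FALSE)
  n_cells <- ncol(ds$normalized)
  if (n_components > min(n_cells, length(hvg)))
    stop("n_components exceeds min(n_cells, n_genes)", call. = FALSE)
  x <- t(as.matrix(ds$normalized[hvg, , drop = FALSE]))  # cells x genes
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  flat <- sds <= 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) in hvg; scaled to 0")
    sds[flat] <- 1
  }
  xs <- sweep(sweep(x, 2, mu), 2, sds, "/")
  xs[xs > clip] <- clip
  xs[xs < -clip] <- -clip
  sv <- if (n_components <= min(dim(xs)) / 3 && min(dim(xs)) > 100) {
    with_seed(1L, irlba::irlba(xs, nv = n_components))
  } else {
    s <- svd(xs, nu = n_components, nv = n_components)
    list(u = s$u, d = s$d[seq_len(n_components)], v = s$v)
  }
  loadings <- sv$v
  rownames(loadings) <- hvg
  colnames(loadings) <- sprintf("PC%d", seq_len(n_components))
  emb <- xs %*% loadings
  rownames(emb) <- ds$cell_table$cell_id
  structure(list(hvg_genes = hvg,
                 scale_means = stats::setNames(mu, hvg),
                 scale_sds = stats::setNames(sds, hvg),
                 clip = clip,
                 pca_loadings = loadings,
                 sdev = sv$d / sqrt(max(1, nrow(xs) - 1)),
                 reference_embedding = emb,
                 neighbor_k = 20L,
                 batch_correction_params = NULL),
            class = "EmbeddingModel")
}

#' @export
print.EmbeddingModel <- function(x, ...) {
  cat(sprintf("EmbeddingModel: %d HVGs, %d PCs, %d reference cells\n",
              length(x$hvg_genes), ncol(x$pca_loadings),
              nrow(x$reference_embedding)))
  invisible(x)
}

#' Mutual-nearest-neighbour batch correction in PC space
#'
#' A simplified integration step: studies are merged onto the largest one in
#' decreasing size order; for each incoming study, mutual nearest neighbours
#' against the already-merged cells define pairwise correction vectors, which
#' are propagated to every cell of the incoming study by Gaussian-kernel
#' smoothing over distance to the paired cells. A single study (or identical
#' batches) yields a correction of (approximately) zero.
#'
#' Like all mutual-nearest-neighbour correction, this assumes the batch
#' displacement is approximately orthogonal to the biological manifold: when
#' the displacement lies inside an isotropic, full-rank data cloud, pairs
#' match points already close in the uncorrected space and the offset is
#' invisible in principle.
#'
#' @param embedding cells x components matrix.
#' @param study_of character/factor of study per cell (row).
#' @param k_mnn neighbours per direction when pairing (default 20; reduced
#'   with a warning for studies with fewer cells).
#' @param sigma kernel bandwidth; default the median distance from cells to
#'   their nearest pair anchor.
#' @return corrected embedding (same shape), with attribute
#'   `batch_correction_params` recording per-study mean corrections.
#' @export
batch_correct <- function(embedding, study_of, k_mnn = 20, sigma = NULL) {
  studies <- names(sort(table(study_of), decreasing = TRUE))
  if (length(studies) < 2) return(embedding)
  corrected <- embedding
  merged <- which(study_of == studies[1])
  params <- list()
  for (s in studies[-1]) {
    idx <- which(study_of == s)
    k <- min(k_mnn, length(idx), length(merged))
    if (k < k_mnn)
      warning("study ", s, " has fewer cells than k_mnn; using k = ", k)
    a <- corrected[merged, , drop = FALSE]
    b <- corrected[idx, , drop = FALSE]
    ab <- knn_search(a, b, k)   # for each b-cell, k nearest in a
    ba <- knn_search(b, a, k)   # for each a-cell, k nearest in b
    # mutual pairs: (i in b, j in a) with j in knn(i) and i in knn(j)
    pair_b <- rep(seq_len(nrow(b)), each = k)
    pair_a <- as.vector(t(ab$idx))
    mutual <- vapply(seq_along(pair_b), function(p)
      pair_b[p] %in% ba$idx[pair_a[p], ], logical(1))
    pb <- pair_b[mutual]; pa <- pair_a[mutual]
    if (!length(pb)) {
      warning("no mutual neighbours between study ", s,
              " and merged set; study left uncorrected")
      merged <- c(merged, idx)
      next
    }
    vecs <- a[pa, , drop = FALSE] - b[pb, , drop = FALSE]
    anchors <- b[pb, , drop = FALSE]
    # smooth over a wide anchor neighbourhood: correction fields must vary
    # slowly relative to within-study structure or they scramble local
    # neighbourhoods
    n_smooth <- min(10 * k_mnn, nrow(anchors))
    nn_anchor <- knn_search(anchors, b, n_smooth)
    if (is.null(sigma)) {
      # bandwidth on the scale of the smoothing neighbourhood itself, so the
      # correction field varies slowly relative to within-study structure
      sig <- median(nn_anchor$dist)
      if (sig <= 0) sig <- 1e-8
    } else sig <- sigma
    # distances offset per cell before exponentiation so that weights never
    # underflow: every cell receives a correction from its nearest anchors
    d2 <- nn_anchor$dist^2
    d2 <- d2 - d2[, 1]
    w <- exp(-d2 / (2 * sig^2))
    w <- w / rowSums(w)
    corr <- matrix(0, nrow(b), ncol(b))
    for (j in seq_len(ncol(nn_anchor$idx)))
      corr <- corr + w[, j] * vecs[nn_anchor$idx[, j], , drop = FALSE]
    corrected[idx, ] <- b + corr
    params[[s]] <- colMeans(corr)
    merged <- c(merged, idx)
  }
  attr(corrected, "batch_correction_params") <- params
  corrected
}

#' Cluster cells with Louvain community detection on a kNN graph
#'
#' Builds the unweighted undirected k-nearest-neighbour graph on Euclidean
#' distance in the embedding and optimises modularity with the Louvain
#' algorithm. Deterministic for a fixed seed.
#'
#' @param embedding cells x components matrix (rownames = cell ids).
#' @param k neighbours per cell (default 20).
#' @param seed integer RNG seed for the Louvain pass.
#' @return a `ClusterResult`: `assignments` (named integer vector),
#'   `modularity`, `markers` (NULL until [cluster_markers()] is run).
#' @export
cluster_cells <- function(embedding, k = 20, seed = 1) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  nn <- knn_search(embedding, embedding, k + 1)
  edges <- cbind(rep(seq_len(n), k), as.vector(nn$idx[, -1, drop = FALSE]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- with_seed(seed, igraph::cluster_louvain(g))
  memb <- as.integer(igraph::membership(cl))
  names(memb) <- rownames(embedding)
  structure(list(assignments = memb,
                 modularity = max(igraph::modularity(cl)),
                 markers = NULL),
            class = "ClusterResult")
}

#' Wilcoxon one-vs-rest cluster markers
#'
#' For each cluster with at least `min_cells` cells, tests every gene's
#' normalized expression against all other cells with the Wilcoxon rank-sum
#' test, reporting the natural-log fold change of de-logged group means
#' (pseudocount 1) and Benjamini-Hochberg adjusted p-values (per cluster).
#'
#' @param ds a normalized `CellDataset`.
#' @param assignments named cluster vector (as from [cluster_cells()]).
#' @param min_cells clusters below this size are skipped with a warning.
#' @return data.frame: `cluster`, `gene_id`, `logFC`, `p`, `p_adj`.
#' @export
cluster_markers <- function(ds, assignments, min_cells = 3) {
  if (is.null(ds$normalized)) stop("run normalize_total first", call. = FALSE)
  idx <- match(ds$cell_table$cell_id, names(assignments))
  cl <- assignments[idx]
  expr <- as.matrix(ds$normalized)
  out <- list()
  for (cid in sort(unique(cl))) {
    members <- which(cl == cid)
    if (length(members) < min_cells) {
      warning("cluster ", cid, " has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    a <- expr[, members, drop = FALSE]
    b <- expr[, -members, drop = FALSE]
    res <- t(vapply(seq_len(nrow(expr)), function(g) {
      xa <- a[g, ]; xb <- b[g, ]
      if (all(xa == xa[1]) && all(xb == xa[1])) return(c(0, 1))
      p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
      c(logfc_means(xa, xb), p)
    }, numeric(2)))
    out[[as.character(cid)]] <- data.frame(
      cluster = cid, gene_id = ds$gene_table$gene_id,
      logFC = res[, 1], p = res[, 2],
      p_adj = p.adjust(res[, 2], "BH"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate clusters by majority true label
#'
#' Maps each cluster to the most frequent cell label among its members —
#' the stand-in for manual marker-based annotation when labels are known
#' (synthetic data) or supplied externally.
#'
#' @param assignments named cluster vector.
#' @param labels named label vector over the same cells.
#' @return named character vector: cluster id -> label.
#' @export
annotate_clusters <- function(assignments, labels) {
  labels <- labels[names(assignments)]
  vapply(split(labels, assignments),
         function(l) names(sort(table(l), decreasing = TRUE))[1], "")
}
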