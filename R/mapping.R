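#' Project query cells into the frozen reference PC space
#'
#' Query genes are matched to the model's highly-variable genes by id,
#' scaled with the reference means and SDs (clipped at the reference clip
#' value), and multiplied by the reference loadings. Genes absent from the
#' query contribute 0 after scaling (i.e. are imputed at the reference
#' mean). The reference itself is never touched: mapping is a frozen
#' transform.
#'
#' @param model an [scale_and_pca()] `EmbeddingModel`.
#' @param query a normalized `CellDataset`.
#' @return query cells x components embedding matrix.
#' @export
project_query <- function(model, query) {
  if (is.null(query$normalized)) stop("run normalize_total first",
                                      call. = FALSE)
  present <- intersect(model$hvg_genes, query$gene_table$gene_id)
  if (length(present) < 0.5 * length(model$hvg_genes))
    stop(sprintf(
      "insufficient feature overlap: only %d of %d model genes in query",
      length(present), length(model$hvg_genes)), call. = FALSE)
  xs <- matrix(0, ncol(query$normalized), length(model$hvg_genes),
               dimnames = list(query$cell_table$cell_id, model$hvg_genes))
  xq <- t(as.matrix(query$normalized[present, , drop = FALSE]))
  xs[, present] <- sweep(sweep(xq, 2, model$scale_means[present]), 2,
                         model$scale_sds[present], "/")
  xs[xs > model$clip] <- model$clip
  xs[xs < -model$clip] <- -model$clip
  xs %*% model$pca_loadings
}

#' Transfer reference labels to query cells by k nearest neighbours
#'
#' Each query cell receives the most prevalent cell type among its k = 30
#' nearest reference cells (Euclidean distance in PC space). Ties are broken
#' by the larger summed inverse distance of the tied labels' neighbours,
#' then lexicographically.
#'
#' @param ref_embedding,query_embedding cells x components matrices.
#' @param ref_labels named (or positional) label vector over reference rows.
#' @param k neighbours (default 30; capped at the reference size).
#' @return list: `labels` (character per query cell), `neighbor_idx`,
#'   `neighbor_dist` (query x k matrices), `neighbor_ids`.
#' @export
transfer_labels <- function(ref_embedding, ref_labels, query_embedding,
                            k = 30) {
  if (!is.null(names(ref_labels)))
    ref_labels <- ref_labels[rownames(ref_embedding)]
  nn <- knn_search(ref_embedding, query_embedding, k)
  eps <- 1e-12
  lab <- vapply(seq_len(nrow(query_embedding)), function(i) {
    l <- ref_labels[nn$idx[i, ]]
    tal <- table(l)
    top <- names(tal)[tal == max(tal)]
    if (length(top) > 1) {
      w <- vapply(top, function(tt)
        sum(1 / (nn$dist[i, l == tt] + eps)), 0)
      top <- top[w == max(w)]
      top <- sort(top)[1]
    }
    top
  }, "")
  ids <- matrix(rownames(ref_embedding)[nn$idx], nrow(nn$idx))
  list(labels = stats::setNames(lab, rownames(query_embedding)),
       neighbor_idx = nn$idx, neighbor_dist = nn$dist, neighbor_ids = ids)
}

#' Confidence scores from neighbour distances
#'
#' The raw score of a query cell is the inverse of its mean distance to its
#' k reference neighbours, `s = 1 / (mean distance + epsilon)`; scores are
#' min-max normalised to \[0, 1\] over the query dataset. Low confidence
#' marks cell states poorly represented in the reference.
#'
#' @param neighbor_dist query x k matrix of neighbour distances.
#' @param epsilon guard against exact-duplicate cells (default 1e-12).
#' @param aggregate `"mean"` (default) or `"median"` of the k distances.
#' @return list: `raw` (positive reals), `confidence` in \[0, 1\]. If all
#'   raw scores are equal, every confidence is set to 1 with a warning.
#' @export
confidence_scores <- function(neighbor_dist, epsilon = 1e-12,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  d <- if (aggregate == "mean") rowMeans(neighbor_dist) else
    apply(neighbor_dist, 1, median)
  raw <- 1 / (d + epsilon)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw scores equal; setting every confidence to 1")
    conf <- rep(1, length(raw))
  } else conf <- (raw - rng[1]) / (rng[2] - rng[1])
  list(raw = raw, confidence = conf)
}

#' Gate confidence scores with a two-component Gaussian mixture
#'
#' Fits a 1-D two-component Gaussian mixture to the confidence scores by EM
#' (k-means initialisation under a fixed seed; convergence when the
#' log-likelihood improves by less than 1e-8, at most 500 iterations). Cells
#' whose posterior for the higher-mean component is at least 0.5 are deemed
#' confidently mapped; the rest are candidate abnormal cells.
#'
#' @param confidences numeric scores in \[0, 1\].
#' @param seed integer for the initialisation.
#' @param max_iter,tol EM controls.
#' @return a `GateModel`: `means`, `vars`, `weights` (length 2),
#'   `confident_component`, `responsibilities`, `confident` (logical),
#'   `loglik` (trace), `degenerate`.
#' @export
gate_confident <- function(confidences, seed = 1, max_iter = 500,
                           tol = 1e-8) {
  x <- as.numeric(confidences)
  n <- length(x)
  if (n < 10) stop("need at least 10 cells to fit the gate", call. = FALSE)
  if (length(unique(x)) < 2) {
    return(structure(list(means = c(x[1], x[1]), vars = c(0, 0),
                          weights = c(0.5, 0.5), confident_component = 2L,
                          responsibilities = matrix(0.5, n, 2),
                          confident = rep(TRUE, n), loglik = numeric(),
                          degenerate = TRUE), class = "GateModel"))
  }
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = 5))
  mu <- as.numeric(km$centers)
  vr <- vapply(1:2, function(j) {
    v <- var(x[km$cluster == j])
    if (!is.finite(v) || v < 1e-8) 1e-8 else v
  }, 0)
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / n
  w <- pmax(w, 1e-6); w <- w / sum(w)
  ll_trace <- numeric()
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, mu[1], sqrt(vr[1])),
                  w[2] * dnorm(x, mu[2], sqrt(vr[2])))
    rowsum_d <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    mu <- colSums(resp * x) / nk
    vr <- vapply(1:2, function(j)
      max(sum(resp[, j] * (x - mu[j])^2) / nk[j], 1e-8), 0)
    w <- nk / n
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  hi <- which.max(mu)
  structure(list(means = mu, vars = vr, weights = w,
                 confident_component = hi,
                 responsibilities = resp,
                 confident = resp[, hi] >= 0.5,
                 loglik = ll_trace, degenerate = FALSE),
            class = "GateModel")
}

#' Map a query dataset onto the reference atlas
#'
#' Convenience pipeline over [project_query()], [transfer_labels()],
#' [confidence_scores()] and [gate_confident()].
#'
#' @param model an `EmbeddingModel`; its `reference_embedding` (corrected if
#'   you stored the corrected one) is the mapping target.
#' @param ref_labels labels over the reference cells.
#' @param query a normalized query `CellDataset`.
#' @param k neighbours for transfer and scoring (default 30).
#' @param seed integer for the mixture gate.
#' @return a `MappingResult`: `cells` data.frame (`cell_id`,
#'   `transferred_label`, `raw_score`, `confidence`, `confident`),
#'   `neighbor_ids`, `gate` (the `GateModel`), `query_embedding`.
#' @export
map_query <- function(model, ref_labels, query, k = 30, seed = 1) {
  qe <- project_query(model, query)
  tr <- transfer_labels(model$reference_embedding, ref_labels, qe, k = k)
  cs <- confidence_scores(tr$neighbor_dist)
  gate <- gate_confident(cs$confidence, seed = seed)
  cells <- data.frame(cell_id = rownames(qe),
                      transferred_label = unname(tr$labels),
                      raw_score = cs$raw, confidence = cs$confidence,
                      confident = gate$confident, stringsAsFactors = FALSE)
  structure(list(cells = cells, neighbor_ids = tr$neighbor_ids,
                 gate = gate, query_embedding = qe),
            class = "MappingResult")
}

#' @export
print.MappingResult <- function(x, ...) {
  cat(sprintf("MappingResult: %d query cells, %.1f%% confident\n",
              nrow(x$cells), 100 * mean(x$cells$confident)))
  invisible(x)
}

#' Disease-versus-healthy differential expression for one cell type
#'
#' Wilcoxon rank-sum test per gene between the query cells and the
#' reference cells of one cell type, on normalized expression. The log fold
#' change is the natural log of the ratio of de-logged group means with
#' pseudocount 1; a gene is significant at `p < p_threshold` and
#' `|logFC| > lfc_threshold` (defaults 0.05 and 0.5). BH-adjusted p-values
#' are reported alongside.
#'
#' @param query,ref normalized `CellDataset`s.
#' @param cell_type the type to compare.
#' @param query_labels,ref_labels named label vectors; default to each
#'   dataset's `label` column.
#' @param p_threshold,lfc_threshold significance thresholds.
#' @return a `DEResult` data.frame: `gene_id`, `logFC`, `p`, `p_adj`,
#'   `significant`, ordered by p.
#' @export
disease_de <- function(query, ref, cell_type, query_labels = NULL,
                       ref_labels = NULL, p_threshold = 0.05,
                       lfc_threshold = 0.5) {
  get_cells <- function(ds, labels, side) {
    if (is.null(labels)) labels <- stats::setNames(ds$cell_table$label,
                                                   ds$cell_table$cell_id)
    ids <- names(labels)[labels == cell_type]
    ids <- intersect(ids, ds$cell_table$cell_id)
    if (!length(ids))
      stop("cell type '", cell_type, "' absent from the ", side,
           " dataset", call. = FALSE)
    if (length(ids) < 3)
      stop("fewer than 3 '", cell_type, "' cells in the ", side,
           " dataset", call. = FALSE)
    as.matrix(ds$normalized[, match(ids, ds$cell_table$cell_id),
                            drop = FALSE])
  }
  shared <- intersect(query$gene_table$gene_id, ref$gene_table$gene_id)
  a <- get_cells(query, query_labels, "query")[shared, , drop = FALSE]
  b <- get_cells(ref, ref_labels, "reference")[shared, , drop = FALSE]
  res <- t(vapply(seq_along(shared), function(g) {
    xa <- a[g, ]; xb <- b[g, ]
    if (all(xa == xa[1]) && all(xb == xa[1])) return(c(0, 1))
    p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
    c(logfc_means(xa, xb), p)
  }, numeric(2)))
  out <- data.frame(gene_id = shared, logFC = res[, 1], p = res[, 2],
                    p_adj = p.adjust(res[, 2], "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < p_threshold & abs(out$logFC) > lfc_threshold
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("DEResult", class(out))
  out
}
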