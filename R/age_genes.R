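#' Gene-level batch correction of normalized expression
#'
#' Removes additive per-study effects from the log-normalized matrix with
#' limma's linear-model batch removal — the gene-space counterpart of the
#' embedding-space MNN correction, used wherever downstream steps need
#' corrected expression values (pseudobulk averaging, disease DE).
#'
#' @param ds a normalized `CellDataset`.
#' @return `ds` with the `corrected` slot filled (dense matrix).
#' @export
correct_expression <- function(ds) {
  if (is.null(ds$normalized)) stop("run normalize_total first", call. = FALSE)
  batch <- factor(ds$cell_table$study_id)
  expr <- as.matrix(ds$normalized)
  ds$corrected <- if (nlevels(batch) > 1)
    limma::removeBatchEffect(expr, batch = batch) else expr
  ds
}

#' Pseudobulk expression per (sample, cell type)
#'
#' Averages expression over the cells of each type in each sample, and
#' computes the eligibility filters for the age-gene screen: a cell type is
#' eligible iff it appears with at least `min_cells` cells in at least
#' `min_samples` samples, and a gene is eligible for a type iff it is
#' detected (count > 0) in more than `detection_fraction` of that type's
#' cells. When `per_sample = TRUE` (default) only samples holding at least
#' `min_cells` cells of the type contribute entries; `FALSE` switches to a
#' total-cell-count reading.
#'
#' @param ds a `CellDataset`; uses `corrected` values when present unless
#'   `values = "normalized"`.
#' @param labels named cell -> type vector; defaults to `cell_table$label`.
#' @param values `"corrected"` (default, falls back to normalized with a
#'   warning) or `"normalized"`.
#' @param min_cells,min_samples,detection_fraction eligibility parameters
#'   (defaults 20, 20, 0.1).
#' @param per_sample eligibility reading, see above.
#' @return a `PseudobulkTable`: `values` (entries x genes matrix, rownames
#'   `sample|cell_type`), `entry_table` (`sample_id`, `cell_type`,
#'   `n_cells`), `eligible_cell_types`, `eligible_genes` (named list per
#'   type).
#' @export
pseudobulk <- function(ds, labels = NULL,
                       values = c("corrected", "normalized"),
                       min_cells = 20, min_samples = 20,
                       detection_fraction = 0.1, per_sample = TRUE) {
  values <- match.arg(values)
  if (is.null(labels)) labels <- stats::setNames(ds$cell_table$label,
                                                 ds$cell_table$cell_id)
  expr <- if (values == "corrected") {
    if (is.null(ds$corrected)) {
      warning("no corrected values; falling back to normalized")
      as.matrix(ds$normalized)
    } else ds$corrected
  } else as.matrix(ds$normalized)
  if (is.null(expr)) stop("run normalize_total first", call. = FALSE)
  lab <- labels[ds$cell_table$cell_id]
  key <- paste(ds$cell_table$sample_id, lab, sep = "|")
  groups <- split(seq_along(key), key)
  vals <- t(vapply(groups, function(ix)
    rowMeans(expr[, ix, drop = FALSE]), numeric(nrow(expr))))
  colnames(vals) <- ds$gene_table$gene_id
  parts <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
  entry_table <- data.frame(sample_id = parts[, 1], cell_type = parts[, 2],
                            n_cells = lengths(groups),
                            stringsAsFactors = FALSE)
  rownames(entry_table) <- NULL

  types <- unique(lab)
  eligible_ct <- character()
  for (tp in types) {
    et <- entry_table[entry_table$cell_type == tp, ]
    ok <- if (per_sample) sum(et$n_cells >= min_cells) >= min_samples else
      (nrow(et) >= min_samples && sum(et$n_cells) >= min_cells)
    if (ok) eligible_ct <- c(eligible_ct, tp)
  }
  if (!length(eligible_ct)) warning("no cell types pass the eligibility filters")
  eligible_genes <- lapply(stats::setNames(nm = sort(eligible_ct)), function(tp) {
    cells <- which(lab == tp)
    det <- Matrix::rowSums(ds$counts[, cells, drop = FALSE] > 0) / length(cells)
    ds$gene_table$gene_id[det > detection_fraction]
  })
  structure(list(values = vals, entry_table = entry_table,
                 eligible_cell_types = sort(eligible_ct),
                 eligible_genes = eligible_genes,
                 params = list(min_cells = min_cells,
                               min_samples = min_samples,
                               detection_fraction = detection_fraction,
                               per_sample = per_sample, values = values)),
            class = "PseudobulkTable")
}

# Entries x genes matrix for one cell type, restricted to samples with
# enough cells (per the table's own parameters) and, optionally, to its
# eligible genes.
pb_matrix <- function(pb, cell_type, eligible_genes_only = TRUE) {
  et <- pb$entry_table
  sel <- et$cell_type == cell_type
  if (pb$params$per_sample) sel <- sel & et$n_cells >= pb$params$min_cells
  m <- pb$values[sel, , drop = FALSE]
  rownames(m) <- et$sample_id[sel]
  if (eligible_genes_only && cell_type %in% names(pb$eligible_genes))
    m <- m[, pb$eligible_genes[[cell_type]], drop = FALSE]
  m
}

#' Screen pseudobulk expression for age-correlated genes
#'
#' Per eligible cell type and eligible gene, Pearson correlation of the
#' pseudobulk expression with donor age; two-sided p-values from the
#' t-distribution with n - 2 degrees of freedom. Genes with p below
#' `p_threshold` are retained as age-related.
#'
#' @param pb a [pseudobulk()] table.
#' @param ages named numeric vector sample_id -> years.
#' @param p_threshold retention threshold on the raw p-value (default 0.01).
#' @param min_samples minimum aged samples per cell type (default 3).
#' @return an `AgeGeneTable` data.frame of retained rows: `cell_type`,
#'   `gene_id`, `pearson_r`, `p`, `direction`; the unfiltered screen is kept
#'   in attribute `full`, skipped zero-variance genes in attribute
#'   `skipped`.
#' @export
age_correlation <- function(pb, ages, p_threshold = 0.01, min_samples = 3) {
  full <- list(); skipped <- list()
  for (tp in pb$eligible_cell_types) {
    m <- pb_matrix(pb, tp)
    age <- ages[rownames(m)]
    keep <- !is.na(age)
    m <- m[keep, , drop = FALSE]; age <- age[keep]
    n <- length(age)
    if (n < min_samples) next
    v <- apply(m, 2, var)
    if (any(v == 0)) {
      skipped[[tp]] <- data.frame(cell_type = tp,
                                  gene_id = colnames(m)[v == 0],
                                  stringsAsFactors = FALSE)
      m <- m[, v > 0, drop = FALSE]
    }
    if (!ncol(m)) next
    r <- as.numeric(cor(age, m))
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    full[[tp]] <- data.frame(cell_type = tp, gene_id = colnames(m),
                             pearson_r = r, p = p,
                             direction = ifelse(r >= 0, "up", "down"),
                             n_samples = n, stringsAsFactors = FALSE)
  }
  full <- if (length(full)) do.call(rbind, full) else
    data.frame(cell_type = character(), gene_id = character(),
               pearson_r = numeric(), p = numeric(),
               direction = character(), n_samples = integer())
  rownames(full) <- NULL
  out <- full[full$p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("AgeGeneTable", class(out))
  out
}

#' How many cell types share each age-related gene
#'
#' @param agt an [age_correlation()] table.
#' @return data.frame: `gene_id`, `n_cell_types`, `direction_consistent`
#'   (all retained rows for the gene share a sign), sorted by sharing count.
#' @export
shared_gene_summary <- function(agt) {
  if (!nrow(agt)) stop("empty AgeGeneTable", call. = FALSE)
  sp <- split(agt$direction, agt$gene_id)
  out <- data.frame(gene_id = names(sp),
                    n_cell_types = lengths(sp),
                    direction_consistent = vapply(sp, function(d)
                      length(unique(d)) == 1, logical(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$n_cell_types, out$gene_id), ]
}

#' Over-representation analysis against local gene sets
#'
#' Hypergeometric upper-tail test of the overlap between a hit list and each
#' gene set (restricted to the universe), with Benjamini-Hochberg adjustment
#' across sets — a local equivalent of web ORA services, run against
#' user-supplied collections.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene ids.
#' @param adj_threshold flag sets with BH-adjusted p below this (default
#'   0.01).
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `selected`.
#' @export
ora_enrichment <- function(hits, gene_sets, universe, adj_threshold = 0.01) {
  hits <- unique(hits); universe <- unique(universe)
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hit genes absent from universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(gene_sets) || any(!lengths(gene_sets)))
    stop("gene sets must be non-empty", call. = FALSE)
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set); k <- length(intersect(set, hits))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out$selected <- out$p_adj < adj_threshold
  out[order(out$p), ]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (one set per line: name, description, genes).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
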