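#' Assemble a multi-sample single-cell count dataset
#'
#' `CellDataset` is the currency of the whole pipeline: a sparse genes x cells
#' count matrix together with aligned cell, gene, and sample annotation
#' tables, plus (after [normalize_total()]) a log-normalized expression matrix
#' and (after [correct_expression()]) a batch-corrected one.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes x cells.
#' @param cell_table data.frame with at least `cell_id`, `sample_id`,
#'   `study_id`; one row per column of `counts`. An optional `label` column
#'   carries cell-type annotations.
#' @param gene_table data.frame with at least `gene_id` and `symbol`; one row
#'   per row of `counts`. Logical `mito`/`ribo` columns are added from symbol
#'   prefixes (`MT-`, `RPL`/`RPS`) when absent.
#' @param sample_table data.frame with at least `sample_id` and `study_id`;
#'   optional `age_years` and `sex`.
#' @param normalized optional real-valued sparse matrix aligned to `counts`.
#'
#' @return an object of class `CellDataset`.
#' @export
cell_dataset <- function(counts, cell_table, gene_table, sample_table,
                         normalized = NULL) {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_table$mito)) {
    gene_table$mito <- startsWith(as.character(gene_table$symbol), "MT-")
  }
  if (is.null(gene_table$ribo)) {
    gene_table$ribo <- grepl("^RP[LS]", as.character(gene_table$symbol))
  }
  rownames(counts) <- gene_table$gene_id
  colnames(counts) <- cell_table$cell_id
  ds <- structure(list(counts = counts,
                       cell_table = as.data.frame(cell_table),
                       gene_table = as.data.frame(gene_table),
                       sample_table = as.data.frame(sample_table),
                       normalized = normalized,
                       corrected = NULL),
                  class = "CellDataset")
  validate_dataset(ds)
  ds
}

#' Validate a CellDataset's structural invariants
#'
#' Checks matrix/table alignment, sample-id referential integrity, and count
#' integrality. Called by all constructors; exported for use after manual
#' surgery on the tables.
#'
#' @param ds a `CellDataset`.
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds) {
  if (ncol(ds$counts) != nrow(ds$cell_table))
    stop("dimension mismatch: counts has ", ncol(ds$counts),
         " columns but cell_table has ", nrow(ds$cell_table), " rows",
         call. = FALSE)
  if (nrow(ds$counts) != nrow(ds$gene_table))
    stop("dimension mismatch: counts has ", nrow(ds$counts),
         " rows but gene_table has ", nrow(ds$gene_table), " rows",
         call. = FALSE)
  missing_s <- setdiff(ds$cell_table$sample_id, ds$sample_table$sample_id)
  if (length(missing_s))
    stop("cells reference samples absent from sample_table: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  x <- ds$counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (!is.null(ds$normalized) &&
      !identical(dim(ds$normalized), dim(ds$counts)))
    stop("normalized matrix not aligned to counts", call. = FALSE)
  invisible(ds)
}

#' @export
print.CellDataset <- function(x, ...) {
  cat(sprintf("CellDataset: %d genes x %d cells, %d samples, %d studies\n",
              nrow(x$counts), ncol(x$counts), nrow(x$sample_table),
              length(unique(x$sample_table$study_id))))
  cat(sprintf("  normalized: %s, batch-corrected: %s\n",
              !is.null(x$normalized), !is.null(x$corrected)))
  invisible(x)
}

#' Subset a CellDataset by cell index
#'
#' @param ds a `CellDataset`.
#' @param cells logical or integer index over columns.
#' @param drop_empty_samples drop sample_table rows that lose all cells.
#' @return the subset `CellDataset`.
#' @export
subset_cells <- function(ds, cells, drop_empty_samples = FALSE) {
  ds$counts <- ds$counts[, cells, drop = FALSE]
  if (!is.null(ds$normalized)) ds$normalized <- ds$normalized[, cells, drop = FALSE]
  if (!is.null(ds$corrected)) ds$corrected <- ds$corrected[, cells, drop = FALSE]
  ds$cell_table <- ds$cell_table[cells, , drop = FALSE]
  rownames(ds$cell_table) <- NULL
  if (drop_empty_samples) {
    keep <- ds$sample_table$sample_id %in% unique(ds$cell_table$sample_id)
    ds$sample_table <- ds$sample_table[keep, , drop = FALSE]
    rownames(ds$sample_table) <- NULL
  }
  validate_dataset(ds)
  ds
}

#' Write a CellDataset to a directory
#'
#' Counts go to `matrix.mtx` (Matrix Market coordinate format, genes x cells,
#' integer), annotations to `cells.tsv` / `genes.tsv` / `samples.tsv`, and the
#' normalized matrix (if present) to `normalized.mtx`.
#'
#' @param ds a `CellDataset`.
#' @param path output directory; created if absent.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
  tsv <- function(df, f) write.table(df, file.path(path, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(ds$cell_table, "cells.tsv")
  tsv(ds$gene_table, "genes.tsv")
  tsv(ds$sample_table, "samples.tsv")
  if (!is.null(ds$normalized))
    Matrix::writeMM(ds$normalized, file.path(path, "normalized.mtx"))
  invisible(path)
}

#' Read a CellDataset from a directory
#'
#' Inverse of [write_dataset()]: expects `matrix.mtx`, `cells.tsv`,
#' `genes.tsv`, `samples.tsv`, and optionally `normalized.mtx`.
#'
#' @param path directory to read.
#' @return a `CellDataset`.
#' @export
read_dataset <- function(path) {
  need <- c("matrix.mtx", "cells.tsv", "genes.tsv", "samples.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("format error: required file '", f, "' missing from ", path,
           call. = FALSE)
  }
  counts <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")),
                        "CsparseMatrix")
  rd <- function(f) read.delim(file.path(path, f), stringsAsFactors = FALSE,
                               colClasses = NA)
  cells <- rd("cells.tsv"); genes <- rd("genes.tsv"); samples <- rd("samples.tsv")
  if (ncol(counts) != nrow(cells))
    stop("format error: matrix.mtx has ", ncol(counts),
         " columns but cells.tsv has ", nrow(cells), " rows", call. = FALSE)
  if (nrow(counts) != nrow(genes))
    stop("format error: matrix.mtx has ", nrow(counts),
         " rows but genes.tsv has ", nrow(genes), " rows", call. = FALSE)
  norm <- NULL
  if (file.exists(file.path(path, "normalized.mtx"))) {
    norm <- methods::as(Matrix::readMM(file.path(path, "normalized.mtx")),
                        "CsparseMatrix")
    dimnames(norm) <- list(genes$gene_id, cells$cell_id)
  }
  cell_dataset(counts, cells, genes, samples, normalized = norm)
}
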