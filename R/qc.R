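#' Quality-control thresholds
#'
#' Explicit per-cell bounds plus the minimum surviving-cell count below which
#' an entire sample is dropped. Defaults follow common single-cell practice:
#' at least 200 detected genes, at most 20% mitochondrial reads, and samples
#' must retain at least 200 cells. All bounds are inclusive on the keep side
#' (a cell is kept when `min <= value <= max`).
#'
#' @param min_umi,max_umi bounds on total UMI counts per cell.
#' @param min_genes,max_genes bounds on detected genes per cell.
#' @param max_mito_fraction,max_ribo_fraction upper bounds on the fraction of
#'   counts in mitochondrial / ribosomal genes.
#' @param min_cells_per_sample samples retaining fewer cells than this after
#'   per-cell filtering are removed entirely.
#' @return a `QCThresholds` list.
#' @export
qc_thresholds <- function(min_umi = 0, max_umi = Inf,
                          min_genes = 200, max_genes = Inf,
                          max_mito_fraction = 0.2, max_ribo_fraction = 1,
                          min_cells_per_sample = 200) {
  thr <- list(min_umi = min_umi, max_umi = max_umi,
              min_genes = min_genes, max_genes = max_genes,
              max_mito_fraction = max_mito_fraction,
              max_ribo_fraction = max_ribo_fraction,
              min_cells_per_sample = min_cells_per_sample)
  if (min_umi > max_umi) stop_config("min_umi", "exceeds max_umi")
  if (min_genes > max_genes) stop_config("min_genes", "exceeds max_genes")
  for (f in c("max_mito_fraction", "max_ribo_fraction"))
    if (thr[[f]] < 0 || thr[[f]] > 1) stop_config(f, "must lie in [0,1]")
  structure(thr, class = "QCThresholds")
}

#' Per-cell QC metrics
#'
#' @param ds a `CellDataset`.
#' @return data.frame with one row per cell: `cell_id`, `sample_id`, `n_umi`,
#'   `n_genes`, `mito_fraction`, `ribo_fraction`. Fractions are 0 for cells
#'   with zero total counts.
#' @export
cell_qc_metrics <- function(ds) {
  tot <- Matrix::colSums(ds$counts)
  ngene <- Matrix::colSums(ds$counts > 0)
  mito <- Matrix::colSums(ds$counts[ds$gene_table$mito, , drop = FALSE])
  ribo <- Matrix::colSums(ds$counts[ds$gene_table$ribo, , drop = FALSE])
  denom <- ifelse(tot > 0, tot, 1)
  data.frame(cell_id = ds$cell_table$cell_id,
             sample_id = ds$cell_table$sample_id,
             n_umi = as.numeric(tot), n_genes = as.numeric(ngene),
             mito_fraction = as.numeric(mito / denom),
             ribo_fraction = as.numeric(ribo / denom),
             stringsAsFactors = FALSE)
}

#' Adaptive per-sample QC cut-offs
#'
#' Optional alternative to fixed bounds: per sample, bounds on log1p(UMI) and
#' log1p(genes) at median +/- k * MAD, mapped back to the count scale.
#'
#' @param ds a `CellDataset`.
#' @param k number of MADs around the per-sample median.
#' @param max_mito_fraction,max_ribo_fraction,min_cells_per_sample passed
#'   through unchanged (fractions are not adapted).
#' @return data.frame of per-sample bounds usable as the `thr` argument of
#'   [qc_filter()].
#' @export
adaptive_qc_thresholds <- function(ds, k = 3, max_mito_fraction = 0.2,
                                   max_ribo_fraction = 1,
                                   min_cells_per_sample = 200) {
  m <- cell_qc_metrics(ds)
  out <- do.call(rbind, lapply(split(m, m$sample_id), function(g) {
    bu <- median(log1p(g$n_umi)) + c(-k, k) * mad(log1p(g$n_umi))
    bg <- median(log1p(g$n_genes)) + c(-k, k) * mad(log1p(g$n_genes))
    data.frame(sample_id = g$sample_id[1],
               min_umi = floor(expm1(bu[1])), max_umi = ceiling(expm1(bu[2])),
               min_genes = floor(expm1(bg[1])),
               max_genes = ceiling(expm1(bg[2])),
               max_mito_fraction = max_mito_fraction,
               max_ribo_fraction = max_ribo_fraction,
               min_cells_per_sample = min_cells_per_sample)
  }))
  rownames(out) <- NULL
  class(out) <- c("QCThresholdsPerSample", class(out))
  out
}

#' Filter cells and samples on QC metrics
#'
#' Removes cells failing any bound, then removes entire samples whose
#' surviving cell count falls below `min_cells_per_sample`. Each removed cell
#' is assigned a single reason (first failing check in the order low_umi,
#' high_umi, low_genes, high_genes, mito_fraction, ribo_fraction,
#' small_sample), so reasons partition the removed set.
#'
#' @param ds a `CellDataset`.
#' @param thr a [qc_thresholds()] object, or a per-sample bounds table from
#'   [adaptive_qc_thresholds()].
#' @return list with `dataset` (the filtered `CellDataset`) and `report`
#'   (list: `sample_summary` data.frame of per-sample cells before/after and
#'   whether the sample was dropped; `cell_reasons` data.frame of removed
#'   cells and their reason).
#' @export
qc_filter <- function(ds, thr = qc_thresholds()) {
  m <- cell_qc_metrics(ds)
  if (is.data.frame(thr)) {
    i <- match(m$sample_id, thr$sample_id)
    if (anyNA(i)) stop("per-sample thresholds missing for: ",
                       paste(unique(m$sample_id[is.na(i)]), collapse = ", "))
    b <- thr[i, , drop = FALSE]
  } else {
    b <- as.data.frame(unclass(thr))[rep(1, nrow(m)), , drop = FALSE]
  }
  reason <- rep(NA_character_, nrow(m))
  checks <- list(low_umi = m$n_umi < b$min_umi,
                 high_umi = m$n_umi > b$max_umi,
                 low_genes = m$n_genes < b$min_genes,
                 high_genes = m$n_genes > b$max_genes,
                 mito_fraction = m$mito_fraction > b$max_mito_fraction,
                 ribo_fraction = m$ribo_fraction > b$max_ribo_fraction)
  for (nm in names(checks)) {
    hit <- checks[[nm]] & is.na(reason)
    reason[hit] <- nm
  }
  keep <- is.na(reason)
  surv <- table(factor(m$sample_id[keep],
                       levels = unique(ds$sample_table$sample_id)))
  min_cps <- if (is.data.frame(thr)) {
    stats::setNames(thr$min_cells_per_sample, thr$sample_id)[names(surv)]
  } else rep(thr$min_cells_per_sample, length(surv))
  dropped_samples <- names(surv)[as.numeric(surv) < min_cps]
  small <- keep & m$sample_id %in% dropped_samples
  reason[small] <- "small_sample"
  keep <- is.na(reason)

  before <- table(factor(m$sample_id,
                         levels = unique(ds$sample_table$sample_id)))
  summary <- data.frame(sample_id = names(before),
                        cells_before = as.numeric(before),
                        cells_after = ifelse(names(before) %in% dropped_samples,
                                             0, as.numeric(surv[names(before)])),
                        dropped = names(before) %in% dropped_samples,
                        stringsAsFactors = FALSE)
  report <- list(sample_summary = summary,
                 cell_reasons = data.frame(cell_id = m$cell_id[!keep],
                                           sample_id = m$sample_id[!keep],
                                           reason = reason[!keep],
                                           stringsAsFactors = FALSE))
  if (!any(keep)) warning("QC thresholds removed all cells")
  out <- subset_cells(ds, keep, drop_empty_samples = TRUE)
  list(dataset = out, report = report)
}

#' Total-count log normalisation
#'
#' Per cell, counts are scaled to a common total and log-transformed:
#' `normalized[g, c] = log(1 + counts[g, c] / total[c] * scale_factor)`.
#' Zero-total cells must be removed by [qc_filter()] first.
#'
#' @param ds a `CellDataset`.
#' @param scale_factor target total per cell (default 10,000).
#' @return `ds` with the `normalized` slot filled (sparse, zero pattern of
#'   the counts preserved).
#' @export
normalize_total <- function(ds, scale_factor = 1e4) {
  tot <- Matrix::colSums(ds$counts)
  if (any(tot == 0))
    stop("cells with zero total counts present; run qc_filter first",
         call. = FALSE)
  norm <- ds$counts
  norm@x <- log1p(norm@x / rep.int(tot, diff(norm@p)) * scale_factor)
  ds$normalized <- norm
  ds
}
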