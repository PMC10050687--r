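#' Per-sample cell-type proportions
#'
#' @param ds a `CellDataset`.
#' @param labels named character vector cell -> cell type; defaults to the
#'   dataset's `label` column.
#' @param unsorted_only if `TRUE` and the sample table carries a logical
#'   `sorted` column, restrict to unsorted samples (sorted samples have
#'   compositions fixed by the sorting strategy, not biology).
#' @return samples x cell-types matrix of proportions (rows sum to 1), with
#'   attribute `n_cells` holding the per-sample totals. Samples with zero
#'   cells are excluded with a warning.
#' @export
sample_proportions <- function(ds, labels = NULL, unsorted_only = FALSE) {
  if (is.null(labels)) {
    if (is.null(ds$cell_table$label))
      stop("no labels supplied and cell_table has no 'label' column",
           call. = FALSE)
    labels <- stats::setNames(ds$cell_table$label, ds$cell_table$cell_id)
  }
  ct <- ds$cell_table
  if (unsorted_only && !is.null(ds$sample_table$sorted)) {
    keep_s <- ds$sample_table$sample_id[!ds$sample_table$sorted]
    ct <- ct[ct$sample_id %in% keep_s, , drop = FALSE]
  }
  lab <- labels[ct$cell_id]
  if (anyNA(lab)) stop("labels do not cover all cells", call. = FALSE)
  tab <- table(factor(ct$sample_id, levels = unique(ct$sample_id)), lab)
  n <- rowSums(tab)
  if (any(n == 0)) {
    warning("samples with zero cells excluded: ",
            paste(rownames(tab)[n == 0], collapse = ", "))
    tab <- tab[n > 0, , drop = FALSE]
    n <- n[n > 0]
  }
  prop <- sweep(unclass(tab), 1, n, "/")
  attr(prop, "n_cells") <- n
  prop
}

#' Test one cell type's proportion for an age trend
#'
#' Ordinary least squares of the per-sample proportion on donor age with the
#' study as a categorical covariate (intercept plus study dummies, reference
#' level the alphabetically first study). The overall p-value is the
#' two-sided t-test on the age coefficient. Per study (with at least
#' `min_study_n` aged samples), a Spearman correlation of proportion with
#' age is reported alongside, with an optional Fisher combination of the
#' per-study p-values.
#'
#' @param proportions samples x types matrix from [sample_proportions()].
#' @param sample_table data.frame with `sample_id`, `study_id`, `age_years`.
#' @param cell_type column of `proportions` to test.
#' @param transform `"identity"` (default; the model is stated on the
#'   percentage scale) or `"logit"` for a robustness check.
#' @param min_study_n minimum aged samples for a per-study Spearman row.
#' @return a `CompositionResult` list: `cell_type`, `beta_age`, `se_age`,
#'   `p_overall`, `beta_project` (study effects), `per_study` data.frame
#'   (`study`, `n`, `spearman_rho`, `spearman_p`), `fisher_p`, `n_samples`.
#' @export
trend_test <- function(proportions, sample_table, cell_type,
                       transform = c("identity", "logit"), min_study_n = 3) {
  transform <- match.arg(transform)
  if (!cell_type %in% colnames(proportions))
    stop("cell type '", cell_type, "' not in proportions table", call. = FALSE)
  i <- match(rownames(proportions), sample_table$sample_id)
  df <- data.frame(prop = proportions[, cell_type],
                   age = sample_table$age_years[i],
                   study = factor(sample_table$study_id[i]))
  df <- df[!is.na(df$age), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 samples with age", call. = FALSE)
  if (length(unique(df$age)) == 1)
    stop("degenerate design: all ages identical", call. = FALSE)
  if (transform == "logit") {
    eps <- 1e-4
    df$prop <- stats::qlogis(pmin(pmax(df$prop, eps), 1 - eps))
  }
  fit <- if (nlevels(droplevels(df$study)) > 1)
    lm(prop ~ age + study, data = droplevels(df)) else
    lm(prop ~ age, data = df)
  sm <- summary(fit)$coefficients
  per_study <- do.call(rbind, lapply(split(df, df$study), function(g) {
    if (nrow(g) < min_study_n) return(NULL)
    ct <- suppressWarnings(cor.test(g$prop, g$age, method = "spearman"))
    data.frame(study = as.character(g$study[1]), n = nrow(g),
               spearman_rho = unname(ct$estimate),
               spearman_p = ct$p.value, stringsAsFactors = FALSE)
  }))
  rownames(per_study) <- NULL
  fisher_p <- NA_real_
  if (!is.null(per_study) && nrow(per_study) > 0 &&
      all(is.finite(per_study$spearman_p))) {
    stat <- -2 * sum(log(pmax(per_study$spearman_p, 1e-300)))
    fisher_p <- stats::pchisq(stat, df = 2 * nrow(per_study),
                              lower.tail = FALSE)
  }
  proj <- grep("^study", rownames(sm), value = TRUE)
  p_overall <- sm["age", "Pr(>|t|)"]
  beta_age <- sm["age", "Estimate"]
  # a constant response carries no evidence of any trend: the t statistic
  # is 0/0 up to rounding noise, so report beta = 0, p = 1
  if (var(df$prop) < .Machine$double.eps^2) {
    beta_age <- 0
    p_overall <- 1
  }
  structure(list(cell_type = cell_type,
                 beta_age = beta_age,
                 se_age = sm["age", "Std. Error"],
                 p_overall = p_overall,
                 beta_project = stats::setNames(sm[proj, "Estimate"],
                                                sub("^study", "", proj)),
                 per_study = per_study %||%
                   data.frame(study = character(), n = integer(),
                              spearman_rho = numeric(),
                              spearman_p = numeric()),
                 fisher_p = fisher_p,
                 n_samples = nrow(df)),
            class = "CompositionResult")
}

#' Age-trend tests for every cell type
#'
#' Runs [trend_test()] across all columns of the proportion table and
#' collects one row per cell type with a BH-adjusted overall p-value.
#'
#' @inheritParams trend_test
#' @return data.frame: `cell_type`, `beta_age`, `se_age`, `p_overall`,
#'   `p_adj`, `fisher_p`, `n_samples`.
#' @export
composition_trends <- function(proportions, sample_table,
                               transform = c("identity", "logit"),
                               min_study_n = 3) {
  transform <- match.arg(transform)
  rows <- lapply(colnames(proportions), function(ctype) {
    r <- trend_test(proportions, sample_table, ctype, transform, min_study_n)
    data.frame(cell_type = ctype, beta_age = r$beta_age, se_age = r$se_age,
               p_overall = r$p_overall, fisher_p = r$fisher_p,
               n_samples = r$n_samples, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_overall, "BH")
  out[order(out$p_overall), ]
}
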