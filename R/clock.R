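#' Fit per-cell-type elastic-net age clocks
#'
#' For each eligible cell type, fits an elastic-net linear model of donor age
#' on that type's age-related pseudobulk genes (glmnet), selecting the
#' penalty by cross-validated mean squared error over sample-level folds.
#' Features are standardised internally (statistics stored in the model);
#' the lambda grid is 100 log-spaced values spanning four decades below the
#' smallest lambda that zeroes all coefficients.
#'
#' @param pb a [pseudobulk()] table.
#' @param agt an [age_correlation()] table restricting each type's features;
#'   pass `NULL` with `features = "all_eligible"` to use every eligible gene.
#' @param ages named sample_id -> years.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param n_folds CV folds (default 10); cell types with fewer samples than
#'   folds are skipped with a warning.
#' @param seed integer controlling the fold assignment, which is made at the
#'   sample level and shared by every cell type.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param lambda optional fixed penalty (skips CV); `0` gives the
#'   unpenalised least-squares limit.
#' @param features `"age_genes"` (default) or `"all_eligible"`.
#' @return a `ClockModel`: per-type records (`genes`, `center`, `scale`,
#'   `coefficients` on the standardised scale, `intercept`, `lambda`) plus
#'   training metadata.
#' @export
fit_clock <- function(pb, agt, ages, alpha = 0.5, n_folds = 10, seed = 1,
                      lambda_rule = c("min", "1se"), lambda = NULL,
                      features = c("age_genes", "all_eligible")) {
  lambda_rule <- match.arg(lambda_rule)
  features <- match.arg(features)
  all_samples <- sort(unique(pb$entry_table$sample_id))
  foldid_of <- with_seed(seed, stats::setNames(
    sample(rep_len(seq_len(n_folds), length(all_samples))), all_samples))
  models <- list()
  for (tp in pb$eligible_cell_types) {
    gset <- if (features == "age_genes") {
      agt$gene_id[agt$cell_type == tp]
    } else pb$eligible_genes[[tp]]
    if (length(gset) < 2) next
    m <- pb_matrix(pb, tp, eligible_genes_only = FALSE)[, gset, drop = FALSE]
    y <- ages[rownames(m)]
    ok <- !is.na(y)
    m <- m[ok, , drop = FALSE]; y <- y[ok]
    if (nrow(m) < n_folds) {
      warning("cell type ", tp, " has fewer samples (", nrow(m),
              ") than folds; skipped")
      next
    }
    ctr <- colMeans(m); scl <- apply(m, 2, sd)
    scl[scl <= 0] <- 1
    xs <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    if (is.null(lambda)) {
      cv <- withCallingHandlers(
        glmnet::cv.glmnet(xs, y, alpha = alpha,
                          foldid = unname(foldid_of[rownames(m)]),
                          standardize = FALSE, nlambda = 100,
                          lambda.min.ratio = 1e-4),
        # informational notice for small folds, not a defect
        warning = function(w) {
          if (grepl("grouped=FALSE enforced", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
      cvm <- min(cv$cvm)
    } else {
      lam <- lambda; cvm <- NA_real_
    }
    # final coefficients refit tightly at the selected penalty
    fit <- glmnet::glmnet(xs, y, alpha = alpha, lambda = lam,
                          standardize = FALSE, thresh = 1e-14, maxit = 1e7)
    cf <- as.numeric(coef(fit, s = lam))
    models[[tp]] <- list(genes = gset, center = ctr, scale = scl,
                         coefficients = stats::setNames(cf[-1], gset),
                         intercept = cf[1], lambda = lam, cv_mse = cvm,
                         n_samples = nrow(m))
  }
  if (!length(models)) stop("no cell type could be fitted", call. = FALSE)
  structure(list(models = models, alpha = alpha, n_folds = n_folds,
                 seed = seed, lambda_rule = lambda_rule,
                 features = features),
            class = "ClockModel")
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf("ClockModel: %d cell types (alpha = %.2f, %d-fold CV, %s rule)\n",
              length(x$models), x$alpha, x$n_folds, x$lambda_rule))
  for (tp in names(x$models)) {
    m <- x$models[[tp]]
    cat(sprintf("  %s: %d features (%d nonzero), lambda = %.4g\n", tp,
                length(m$genes), sum(m$coefficients != 0), m$lambda))
  }
  invisible(x)
}

clock_predict_type <- function(model_tp, m) {
  xs <- sweep(sweep(m[, model_tp$genes, drop = FALSE], 2, model_tp$center),
              2, model_tp$scale, "/")
  drop(xs %*% model_tp$coefficients) + model_tp$intercept
}

#' Predict sample ages from pseudobulk with a fitted clock
#'
#' Each cell type present both in the model and in the sample yields a
#' linear prediction; the sample's predicted age is the median across cell
#' types (mean of the two central values for even counts). When a
#' `mapping_gate` is supplied together with the query dataset, the
#' pseudobulk is recomputed from confidently mapped cells only before
#' predicting.
#'
#' @param model a [fit_clock()] model.
#' @param pb a [pseudobulk()] table for the samples to predict (ignored when
#'   a gate is given).
#' @param mapping_gate optional `MappingResult` from [map_query()].
#' @param ds,labels query `CellDataset` and labels, required with
#'   `mapping_gate`.
#' @param min_cells minimum cells per (sample, type) entry when recomputing
#'   gated pseudobulk (default 10; reference-scale eligibility does not
#'   apply to a handful of query samples).
#' @return data.frame: `sample_id`, `predicted_age`, `n_cell_types_used`;
#'   per-type predictions in attribute `per_cell_type`. Negative predicted
#'   ages are reported as-is and flagged in a `negative` column.
#' @export
predict_age <- function(model, pb = NULL, mapping_gate = NULL, ds = NULL,
                        labels = NULL, min_cells = 10) {
  if (!is.null(mapping_gate)) {
    if (is.null(ds)) stop("mapping_gate requires the query dataset",
                          call. = FALSE)
    if (is.null(labels))
      labels <- stats::setNames(mapping_gate$cells$transferred_label,
                                mapping_gate$cells$cell_id)
    conf <- mapping_gate$cells$cell_id[mapping_gate$cells$confident]
    ds <- subset_cells(ds, ds$cell_table$cell_id %in% conf)
    pb <- pseudobulk(ds, labels = labels, values = "normalized",
                     min_cells = min_cells, min_samples = 1)
  }
  if (is.null(pb)) stop("supply a pseudobulk table or a mapping gate",
                        call. = FALSE)
  et <- pb$entry_table
  types <- intersect(names(model$models), unique(et$cell_type))
  if (!length(types))
    stop("no cell type shared between model and pseudobulk", call. = FALSE)
  vals <- pb$values
  rownames(vals) <- paste(et$sample_id, et$cell_type, sep = "|")
  samples <- unique(et$sample_id)
  per_type <- matrix(NA_real_, length(samples), length(types),
                     dimnames = list(samples, types))
  for (tp in types) {
    sel <- et$cell_type == tp
    if (pb$params$per_sample) sel <- sel & et$n_cells >= pb$params$min_cells
    if (!any(sel)) next
    m <- vals[sel, , drop = FALSE]
    pred <- clock_predict_type(model$models[[tp]], m)
    per_type[et$sample_id[sel], tp] <- pred
  }
  out <- data.frame(
    sample_id = samples,
    predicted_age = apply(per_type, 1, function(v) median(v[!is.na(v)])),
    n_cell_types_used = rowSums(!is.na(per_type)),
    stringsAsFactors = FALSE)
  out$negative <- !is.na(out$predicted_age) & out$predicted_age < 0
  rownames(out) <- NULL
  attr(out, "per_cell_type") <- per_type
  out
}

#' Cross-validated evaluation of the clock pipeline
#'
#' Sample-level K-fold cross-validation of the whole clock procedure: within
#' each training fold the age-gene screen is re-run (no feature-selection
#' leakage), per-type clocks are fitted, and held-out samples predicted.
#' Reports the Pearson correlation and the median absolute error between
#' out-of-fold predicted and chronological ages.
#'
#' @param pb a [pseudobulk()] table over all samples.
#' @param ages named sample_id -> years.
#' @param alpha,p_threshold,lambda_rule passed to [fit_clock()] /
#'   [age_correlation()].
#' @param n_folds outer folds (default 10); must not exceed the number of
#'   aged samples.
#' @param seed integer driving outer and inner fold assignments.
#' @return list: `predictions` (data.frame of oof predictions), `overall_r`,
#'   `median_abs_error`, `per_fold` data.frame.
#' @export
evaluate_clock <- function(pb, ages, alpha = 0.5, p_threshold = 0.01,
                           n_folds = 10, seed = 1, lambda_rule = "min") {
  samples <- sort(intersect(unique(pb$entry_table$sample_id),
                            names(ages)[!is.na(ages)]))
  if (n_folds > length(samples))
    stop("n_folds exceeds the number of samples with age", call. = FALSE)
  fold <- with_seed(seed, stats::setNames(
    sample(rep_len(seq_len(n_folds), length(samples))), samples))
  preds <- list()
  for (f in seq_len(n_folds)) {
    train <- samples[fold != f]; test <- samples[fold == f]
    pb_train <- subset_pseudobulk(pb, train)
    pb_test <- subset_pseudobulk(pb, test)
    agt <- age_correlation(pb_train, ages, p_threshold = p_threshold)
    if (!nrow(agt)) next
    cm <- fit_clock(pb_train, agt, ages, alpha = alpha,
                    n_folds = min(10, length(train)), seed = seed + f,
                    lambda_rule = lambda_rule)
    pr <- predict_age(cm, pb_test)
    pr$fold <- f
    preds[[f]] <- pr
  }
  preds <- do.call(rbind, preds)
  if (is.null(preds) || !nrow(preds))
    return(list(predictions = NULL, overall_r = NA_real_,
                median_abs_error = NA_real_, per_fold = NULL))
  preds$true_age <- ages[preds$sample_id]
  ok <- !is.na(preds$predicted_age)
  r <- if (sum(ok) > 2 && sd(preds$predicted_age[ok]) > 0)
    cor(preds$predicted_age[ok], preds$true_age[ok]) else NA_real_
  per_fold <- do.call(rbind, lapply(split(preds[ok, ], preds$fold[ok]),
    function(g) data.frame(fold = g$fold[1], n = nrow(g),
      mae = median(abs(g$predicted_age - g$true_age)))))
  list(predictions = preds, overall_r = r,
       median_abs_error = median(abs(preds$predicted_age[ok] -
                                     preds$true_age[ok])),
       per_fold = per_fold)
}

# Restrict a PseudobulkTable to a set of samples, keeping the eligibility
# decisions made on the full table (eligibility is a property of the cohort,
# not of a CV fold).
subset_pseudobulk <- function(pb, samples) {
  keep <- pb$entry_table$sample_id %in% samples
  pb$values <- pb$values[keep, , drop = FALSE]
  pb$entry_table <- pb$entry_table[keep, , drop = FALSE]
  rownames(pb$entry_table) <- NULL
  pb
}
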