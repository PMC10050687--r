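#' Specify one simulated cell type
#'
#' @param name cell-type label.
#' @param base_proportion expected proportion of this type at the cohort's
#'   mid age; base proportions across types must sum to 1.
#' @param proportion_age_slope change in expected proportion per year of age
#'   (proportion scale; expected proportions are clipped to (0.001, 0.999)
#'   and renormalised, so slopes that sum to zero across types are recovered
#'   exactly).
#' @param marker_genes integer gene indices upregulated in this type.
#' @param marker_log_fc log-scale boost applied to marker genes (natural log).
#' @param n_age_genes number of genes whose mean log-expression drifts
#'   linearly with donor age in this type.
#' @param age_gene_slope absolute mean log-expression change per year for the
#'   planted age genes (signs alternate across genes).
#' @return a `CellTypeSpec` list.
#' @export
cell_type_spec <- function(name, base_proportion, proportion_age_slope = 0,
                           marker_genes = integer(), marker_log_fc = 2,
                           n_age_genes = 0, age_gene_slope = 0) {
  structure(list(name = name, base_proportion = base_proportion,
                 proportion_age_slope = proportion_age_slope,
                 marker_genes = as.integer(marker_genes),
                 marker_log_fc = marker_log_fc,
                 n_age_genes = as.integer(n_age_genes),
                 age_gene_slope = age_gene_slope),
            class = "CellTypeSpec")
}

#' Configure a synthetic multi-study cohort
#'
#' Defines the generative model for [generate_reference()] and
#' [generate_query()]: a negative-binomial count model whose per-cell-type
#' mean profile is modulated by planted age-gene slopes and per-study
#' multiplicative (lognormal) batch factors, with per-sample cell-type
#' composition drawn multinomially from age-dependent expected proportions
#' and donor ages drawn uniformly over `age_range` (or from `ages` when
#' given).
#'
#' @param cell_types list of [cell_type_spec()] objects.
#' @param n_studies,samples_per_study cohort layout.
#' @param age_range donor age span in years (default 2 to 84).
#' @param ages optional discrete set of ages to sample from instead of the
#'   uniform draw.
#' @param n_genes total genes simulated (a handful carry `MT-`/`RPL`/`RPS`
#'   symbols so QC fractions are exercised).
#' @param batch_sd log-scale SD of per-study gene-wise multiplicative batch
#'   factors.
#' @param mean_cells_per_sample Poisson mean of cells per sample.
#' @param sequencing_depth expected UMIs per cell.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); ignored for `count_model = "poisson"`.
#' @param count_model `"nb"` (default) or `"poisson"`.
#' @param seed integer; the generator is deterministic given the config.
#' @return a `CohortConfig` list.
#' @export
cohort_config <- function(cell_types,
                          n_studies = 3, samples_per_study = 8,
                          age_range = c(2, 84), ages = NULL,
                          n_genes = 500, batch_sd = 0.15,
                          mean_cells_per_sample = 300,
                          sequencing_depth = 2000,
                          dispersion = 0.3,
                          count_model = c("nb", "poisson"),
                          seed = 1) {
  count_model <- match.arg(count_model)
  cfg <- structure(list(cell_types = cell_types, n_studies = n_studies,
                        samples_per_study = samples_per_study,
                        age_range = age_range, ages = ages,
                        n_genes = n_genes, batch_sd = batch_sd,
                        mean_cells_per_sample = mean_cells_per_sample,
                        sequencing_depth = sequencing_depth,
                        dispersion = dispersion, count_model = count_model,
                        seed = seed),
                   class = "CohortConfig")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_pos_int <- function(x, f) {
    if (!is.numeric(cfg[[x]]) || length(cfg[[x]]) != 1 || cfg[[x]] < 1 ||
        cfg[[x]] != round(cfg[[x]])) stop_config(x, "must be a positive integer")
  }
  chk_pos_int("n_studies"); chk_pos_int("samples_per_study")
  chk_pos_int("n_genes"); chk_pos_int("mean_cells_per_sample")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    stop_config("age_range", "must be (min, max) with min < max")
  if (cfg$batch_sd < 0) stop_config("batch_sd", "must be nonnegative")
  if (cfg$sequencing_depth <= 0) stop_config("sequencing_depth", "must be positive")
  if (cfg$dispersion <= 0) stop_config("dispersion", "must be positive")
  if (abs(cfg$seed) >= 2^31 - 10 || cfg$seed != round(cfg$seed))
    stop_config("seed", "must be a 32-bit integer")
  if (!length(cfg$cell_types)) stop_config("cell_types", "must be non-empty")
  props <- vapply(cfg$cell_types, `[[`, 0, "base_proportion")
  if (any(props <= 0 | props >= 1))
    stop_config("cell_types", "has base_proportion outside (0,1)")
  if (abs(sum(props) - 1) > 1e-8)
    stop_config("cell_types", "base_proportions must sum to 1")
  mk <- unlist(lapply(cfg$cell_types, `[[`, "marker_genes"))
  if (anyDuplicated(mk))
    stop_config("cell_types", "marker_genes must be disjoint across types")
  if (length(mk) && (max(mk) > cfg$n_genes || min(mk) < 1))
    stop_config("cell_types", "marker_genes indices outside 1..n_genes")
  nag <- vapply(cfg$cell_types, `[[`, 0L, "n_age_genes")
  if (any(nag > cfg$n_genes))
    stop_config("cell_types", "n_age_genes exceeds n_genes")
  invisible(cfg)
}

# Deterministic planted structure shared by reference and query: gene table,
# baseline log-means, marker boosts, age-gene assignments, batch factors.
build_generative_model <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_mito <- 8L; n_ribo <- 12L
    sym <- sprintf("GENE%04d", seq_len(n))
    sym[seq_len(n_mito)] <- sprintf("MT-SIM%d", seq_len(n_mito))
    sym[n_mito + seq_len(n_ribo)] <-
      c(sprintf("RPL-SIM%d", 1:6), sprintf("RPS-SIM%d", 1:6))
    gene_table <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                             symbol = sym, stringsAsFactors = FALSE)
    base <- rnorm(n, 0, 1)
    types <- vapply(cfg$cell_types, `[[`, "", "name")
    boost <- matrix(0, n, length(types), dimnames = list(NULL, types))
    for (ct in cfg$cell_types) boost[ct$marker_genes, ct$name] <- ct$marker_log_fc
    housek <- seq_len(n_mito + n_ribo)
    pool <- setdiff(seq_len(n), c(housek, unlist(lapply(cfg$cell_types,
                                                        `[[`, "marker_genes"))))
    age_rows <- list()
    for (ct in cfg$cell_types) {
      if (ct$n_age_genes == 0) next
      if (ct$n_age_genes > length(pool))
        stop_config("cell_types",
                    "requests more age genes than unassigned genes remain")
      g <- sample(pool, ct$n_age_genes)
      pool <- setdiff(pool, g)
      slope <- ct$age_gene_slope * rep_len(c(1, -1), length(g))
      age_rows[[ct$name]] <- data.frame(cell_type = ct$name, gene_index = g,
                                        gene_id = gene_table$gene_id[g],
                                        slope = slope, stringsAsFactors = FALSE)
    }
    age_genes <- if (length(age_rows)) do.call(rbind, age_rows) else
      data.frame(cell_type = character(), gene_index = integer(),
                 gene_id = character(), slope = numeric())
    rownames(age_genes) <- NULL
    batch <- matrix(rnorm(n * cfg$n_studies, 0, cfg$batch_sd), n, cfg$n_studies,
                    dimnames = list(NULL, sprintf("ST%d", seq_len(cfg$n_studies))))
    list(gene_table = gene_table, base = base, boost = boost,
         age_genes = age_genes, batch = batch, mid_age = mean(cfg$age_range))
  })
}

# Expected cell-type proportions at a given age: linear trend on the
# proportion scale, clipped to (0.001, 0.999), renormalised.
expected_proportions <- function(cfg, age) {
  mid <- mean(cfg$age_range)
  p <- vapply(cfg$cell_types, function(ct)
    ct$base_proportion + ct$proportion_age_slope * (age - mid), 0)
  p <- pmin(pmax(p, 0.001), 0.999)
  stats::setNames(p / sum(p), vapply(cfg$cell_types, `[[`, "", "name"))
}

#' Draw per-sample cell-type compositions
#'
#' The composition half of the generative model on its own: expected
#' proportions follow the configured linear-in-age trend and realized counts
#' are multinomial. Used internally by [generate_reference()] and directly
#' by calibration studies that do not need gene expression.
#'
#' @param cfg a [cohort_config()].
#' @param ages named numeric vector of sample ages (names become sample ids).
#' @param seed integer.
#' @return list with `counts` (samples x types) and `proportions` matrices.
#' @export
simulate_composition <- function(cfg, ages, seed) {
  with_seed(seed, {
    types <- vapply(cfg$cell_types, `[[`, "", "name")
    cnt <- matrix(0L, length(ages), length(types),
                  dimnames = list(names(ages), types))
    for (i in seq_along(ages)) {
      n <- max(1L, rpois(1, cfg$mean_cells_per_sample))
      cnt[i, ] <- rmultinom(1, n, expected_proportions(cfg, ages[i]))
    }
    list(counts = cnt, proportions = cnt / rowSums(cnt))
  })
}

# Draw the count block for one (sample, type): genes x k sparse-ready matrix.
draw_count_block <- function(lograte, k, cfg) {
  r <- exp(lograte)
  mu <- cfg$sequencing_depth * r / sum(r)
  n <- length(mu)
  x <- if (cfg$count_model == "poisson") rpois(n * k, rep(mu, k)) else
    rnbinom(n * k, mu = rep(mu, k), size = 1 / cfg$dispersion)
  matrix(x, nrow = n, ncol = k)
}

draw_cohort <- function(cfg, model, sample_table, batch_of, shift = NULL) {
  types <- vapply(cfg$cell_types, `[[`, "", "name")
  blocks <- vector("list", nrow(sample_table))
  cells <- vector("list", nrow(sample_table))
  abnormal <- character()
  for (i in seq_len(nrow(sample_table))) {
    sid <- sample_table$sample_id[i]
    age <- sample_table$age_years[i]
    comp <- rmultinom(1, max(1L, rpois(1, cfg$mean_cells_per_sample)),
                      expected_proportions(cfg, age))[, 1]
    bcol <- batch_of[i]
    smat <- NULL; labels <- character()
    for (t in seq_along(types)) {
      k <- comp[t]
      if (k == 0) next
      lograte <- model$base + model$boost[, types[t]]
      ag <- model$age_genes[model$age_genes$cell_type == types[t], ]
      if (nrow(ag))
        lograte[ag$gene_index] <- lograte[ag$gene_index] +
          ag$slope * (age - model$mid_age)
      if (!is.na(bcol)) lograte <- lograte + model$batch[, bcol]
      n_ab <- 0L
      if (!is.null(shift) && types[t] == shift$cell_type && k > 0)
        n_ab <- rbinom(1, k, shift$fraction)
      blk <- draw_count_block(lograte, k - n_ab, cfg)
      if (n_ab > 0) {
        lr2 <- lograte
        lr2[shift$gene_index] <- lr2[shift$gene_index] + shift$delta
        blk <- cbind(blk, draw_count_block(lr2, n_ab, cfg))
      }
      smat <- if (is.null(smat)) blk else cbind(smat, blk)
      labels <- c(labels, rep(types[t], k))
      if (n_ab > 0) {
        ids_t <- sprintf("%s_C%04d", sid,
                         length(labels) - k + seq_len(k))
        abnormal <- c(abnormal, ids_t[(k - n_ab + 1):k])
      }
    }
    cell_id <- sprintf("%s_C%04d", sid, seq_along(labels))
    cells[[i]] <- data.frame(cell_id = cell_id, sample_id = sid,
                             study_id = sample_table$study_id[i],
                             label = labels, stringsAsFactors = FALSE)
    blocks[[i]] <- methods::as(Matrix::Matrix(smat, sparse = TRUE),
                               "CsparseMatrix")
  }
  counts <- do.call(cbind, blocks)
  cell_table <- do.call(rbind, cells)
  list(counts = counts, cell_table = cell_table, abnormal = abnormal)
}

#' Generate a synthetic multi-study reference cohort
#'
#' Draws a full single-cell cohort from the configured generative model and
#' returns it together with the planted ground truth: true ages, true
#' composition slopes, planted age genes, and true per-cell labels.
#'
#' @param cfg a [cohort_config()].
#' @return list with `dataset` (a `CellDataset`; `cell_table$label` carries
#'   the true type) and `truth` (a `TruthBundle` list: `sample_ages`,
#'   `trend_cell_types`, `age_genes`, `abnormal_cells` (empty here),
#'   `true_labels`).
#' @export
generate_reference <- function(cfg) {
  validate_config(cfg)
  model <- build_generative_model(cfg)
  with_seed(cfg$seed + 1L, {
    st <- expand.grid(s = seq_len(cfg$samples_per_study),
                      b = seq_len(cfg$n_studies))
    sample_table <- data.frame(
      sample_id = sprintf("ST%d_S%02d", st$b, st$s),
      study_id = sprintf("ST%d", st$b),
      age_years = if (is.null(cfg$ages))
        runif(nrow(st), cfg$age_range[1], cfg$age_range[2]) else
        sample(cfg$ages, nrow(st), replace = TRUE),
      sex = sample(c("F", "M"), nrow(st), replace = TRUE),
      stringsAsFactors = FALSE)
    drawn <- draw_cohort(cfg, model, sample_table,
                         batch_of = match(sample_table$study_id,
                                          colnames(model$batch)))
    ds <- cell_dataset(drawn$counts, drawn$cell_table, model$gene_table,
                       sample_table)
    truth <- list(
      sample_ages = stats::setNames(sample_table$age_years,
                                    sample_table$sample_id),
      trend_cell_types = stats::setNames(
        vapply(cfg$cell_types, `[[`, 0, "proportion_age_slope"),
        vapply(cfg$cell_types, `[[`, "", "name")),
      age_genes = model$age_genes,
      abnormal_cells = character(),
      true_labels = stats::setNames(drawn$cell_table$label,
                                    drawn$cell_table$cell_id))
    class(truth) <- "TruthBundle"
    list(dataset = ds, truth = truth)
  })
}

#' Generate a query cohort with optional planted abnormal cells
#'
#' Query samples are drawn from the same generative model as the reference
#' (no study batch factor: the query is a fresh study), except that a
#' fraction of cells of one type carry an ectopic activation program: their
#' mean log-expression is raised by `shift_magnitude` on a random sparse set
#' of `n_shift_genes` genes, mimicking malignant cells expressing a program
#' absent from their healthy counterparts. Up-regulation (rather than random
#' signs) is deliberate: lowering genes a cell type barely expresses is a
#' near no-op on counts, so it would not displace the cells, and the planted
#' magnitude would no longer control the real displacement.
#'
#' @param reference_config the [cohort_config()] the reference was built
#'   from; planted genes, markers and baselines are re-derived from it.
#' @param n_samples query samples to draw.
#' @param abnormal_fraction probability that a cell of the shifted type is
#'   abnormal.
#' @param shift_magnitude per-gene mean log-expression displacement.
#' @param shifted_cell_type which type carries the abnormal program.
#' @param seed integer for the query draws.
#' @param n_shift_genes sparse support of the displacement (default 50).
#' @param shift_gene_pool `"markers"` (default) draws the activated genes
#'   from the marker panels of the *other* cell types — ectopic expression,
#'   the kind of aberration that lives in the variable-gene feature space a
#'   reference embedding can see; `"random"` draws them from all
#'   non-housekeeping genes.
#' @return list with `dataset` and `truth`; `truth$abnormal_cells` flags the
#'   shifted cells and `truth$shift_genes` records the displaced genes.
#' @export
generate_query <- function(reference_config, n_samples,
                           abnormal_fraction = 0, shift_magnitude = 0,
                           shifted_cell_type = NULL, seed = 1,
                           n_shift_genes = 50,
                           shift_gene_pool = c("markers", "random")) {
  shift_gene_pool <- match.arg(shift_gene_pool)
  cfg <- reference_config
  validate_config(cfg)
  types <- vapply(cfg$cell_types, `[[`, "", "name")
  if (abnormal_fraction < 0 || abnormal_fraction >= 1)
    stop_config("abnormal_fraction", "must lie in [0, 1)")
  if (abnormal_fraction > 0 || !is.null(shifted_cell_type)) {
    if (is.null(shifted_cell_type) || !shifted_cell_type %in% types)
      stop("unknown shifted_cell_type: ",
           shifted_cell_type %||% "<missing>", call. = FALSE)
  }
  model <- build_generative_model(cfg)
  with_seed(seed, {
    sample_table <- data.frame(
      sample_id = sprintf("QRY_S%02d", seq_len(n_samples)),
      study_id = "QUERY",
      age_years = if (is.null(cfg$ages))
        runif(n_samples, cfg$age_range[1], cfg$age_range[2]) else
        sample(cfg$ages, n_samples, replace = TRUE),
      sex = sample(c("F", "M"), n_samples, replace = TRUE),
      stringsAsFactors = FALSE)
    shift <- NULL
    shift_genes <- data.frame(gene_id = character(), delta = numeric())
    if (!is.null(shifted_cell_type) && abnormal_fraction > 0 &&
        shift_magnitude > 0) {
      markers <- unlist(lapply(
        cfg$cell_types[types != shifted_cell_type], `[[`, "marker_genes"))
      pool <- if (shift_gene_pool == "markers" &&
                  length(markers) >= n_shift_genes) markers else
        which(!startsWith(model$gene_table$symbol, "MT-") &
              !grepl("^RP[LS]", model$gene_table$symbol))
      g <- sample(pool, min(n_shift_genes, length(pool)))
      delta <- rep(shift_magnitude, length(g))
      shift <- list(cell_type = shifted_cell_type, fraction = abnormal_fraction,
                    gene_index = g, delta = delta)
      shift_genes <- data.frame(gene_id = model$gene_table$gene_id[g],
                                delta = delta, stringsAsFactors = FALSE)
    }
    drawn <- draw_cohort(cfg, model, sample_table,
                         batch_of = rep(NA_integer_, n_samples),
                         shift = shift)
    ds <- cell_dataset(drawn$counts, drawn$cell_table, model$gene_table,
                       sample_table)
    truth <- list(
      sample_ages = stats::setNames(sample_table$age_years,
                                    sample_table$sample_id),
      trend_cell_types = stats::setNames(
        vapply(cfg$cell_types, `[[`, 0, "proportion_age_slope"), types),
      age_genes = model$age_genes,
      abnormal_cells = drawn$abnormal,
      true_labels = stats::setNames(drawn$cell_table$label,
                                    drawn$cell_table$cell_id),
      shift_genes = shift_genes)
    class(truth) <- "TruthBundle"
    list(dataset = ds, truth = truth)
  })
}

#' Write / read a TruthBundle as TSV files
#'
#' Serialises the planted ground truth (`sample_ages.tsv`,
#' `trend_cell_types.tsv`, `age_genes.tsv`, `abnormal_cells.tsv`,
#' `true_labels.tsv`, `shift_genes.tsv`) so analysis drivers can round-trip
#' it alongside the datasets.
#'
#' @param truth a `TruthBundle`.
#' @param path directory.
#' @return `path` (write) or a `TruthBundle` (read).
#' @export
write_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, f) write.table(df, file.path(path, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(data.frame(sample_id = names(truth$sample_ages),
                 age_years = unname(truth$sample_ages)), "sample_ages.tsv")
  tsv(data.frame(cell_type = names(truth$trend_cell_types),
                 proportion_age_slope = unname(truth$trend_cell_types)),
      "trend_cell_types.tsv")
  tsv(truth$age_genes, "age_genes.tsv")
  tsv(data.frame(cell_id = truth$abnormal_cells), "abnormal_cells.tsv")
  tsv(data.frame(cell_id = names(truth$true_labels),
                 label = unname(truth$true_labels)), "true_labels.tsv")
  if (!is.null(truth$shift_genes)) tsv(truth$shift_genes, "shift_genes.tsv")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rd <- function(f) read.delim(file.path(path, f), stringsAsFactors = FALSE)
  ages <- rd("sample_ages.tsv"); trend <- rd("trend_cell_types.tsv")
  ab <- rd("abnormal_cells.tsv"); labs <- rd("true_labels.tsv")
  truth <- list(
    sample_ages = stats::setNames(ages$age_years, ages$sample_id),
    trend_cell_types = stats::setNames(trend$proportion_age_slope,
                                       trend$cell_type),
    age_genes = rd("age_genes.tsv"),
    abnormal_cells = as.character(ab$cell_id),
    true_labels = stats::setNames(labs$label, labs$cell_id))
  if (file.exists(file.path(path, "shift_genes.tsv")))
    truth$shift_genes <- rd("shift_genes.tsv")
  class(truth) <- "TruthBundle"
  truth
}

#' A ready-made bone-marrow-like cohort configuration
#'
#' Four populations loosely shaped on bone marrow (T, B, monocyte, plasma)
#' with disjoint 20-gene marker panels, balanced composition trends, and
#' planted age genes; convenient for examples and desk-scale runs.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `CohortConfig`.
#' @export
example_cohort_config <- function(...) {
  ct <- list(
    cell_type_spec("Tcell", 0.40, proportion_age_slope = 0.0015,
                   marker_genes = 101:120, n_age_genes = 25,
                   age_gene_slope = 0.015),
    cell_type_spec("Bcell", 0.25, proportion_age_slope = -0.0015,
                   marker_genes = 121:140, n_age_genes = 25,
                   age_gene_slope = 0.015),
    cell_type_spec("Mono", 0.25, proportion_age_slope = 0,
                   marker_genes = 141:160, n_age_genes = 25,
                   age_gene_slope = 0.015),
    cell_type_spec("Plasma", 0.10, proportion_age_slope = 0,
                   marker_genes = 161:180, n_age_genes = 0))
  cohort_config(cell_types = ct, ...)
}
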