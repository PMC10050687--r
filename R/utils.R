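# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so generators never clobber a session's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Exact Euclidean k nearest neighbours of `query` rows among `ref` rows.
# Thin wrapper so the backend is swappable in one place.
knn_search <- function(ref, query, k) {
  stopifnot(ncol(ref) == ncol(query))
  k <- min(k, nrow(ref))
  res <- RANN::nn2(data = ref, query = query, k = k, treetype = "kd",
                   searchtype = "standard")
  list(idx = res$nn.idx, dist = res$nn.dists)
}

# log fold change of group means on the de-logged scale with pseudocount 1:
# ln((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1)). `x`, `y` are vectors of
# log-normalized expression for one gene.
logfc_means <- function(x, y) {
  log((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))
}

# Row-wise means and sample variances of a sparse (genes x cells) matrix
# without densifying.
sparse_row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  if (n < 2) return(list(mean = mu, var = rep(0, nrow(m))))
  ex2 <- Matrix::rowMeans(m^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0
  list(mean = mu, var = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
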