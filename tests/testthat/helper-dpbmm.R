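# Small fixture builders shared across test files.

# A tidy beta-value table from a matrix of values.
make_beta_tbl <- function(values, n = nrow(values)) {
  m <- as.matrix(values)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- paste0("cg", seq_len(ncol(m)))
  tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
}

# Random beta-value table with given shape.
random_beta_tbl <- function(n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_beta_tbl(matrix(stats::runif(n * L, 0.05, 0.95), n, L))
}

# Prepared internal data cache for sampler-level tests.
make_cache <- function(tbl, prior_only = FALSE) {
  dpbmm:::make_data_cache(
    dpbmm:::as_beta_matrix(clip_beta_values(tbl)), prior_only = prior_only)
}

# Batch-means Monte Carlo standard error for an autocorrelated chain.
batch_se <- function(x, n_batches = 30) {
  n <- length(x)
  size <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
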