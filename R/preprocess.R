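#' Clip beta values away from the unit-interval boundaries
#'
#' The beta log density is undefined at 0 and 1, yet array exports routinely
#' contain exact zeros and ones. Clipping maps every entry into
#' `[eps, 1 - eps]` and leaves interior values untouched; it is idempotent.
#'
#' @param data Beta-value table: a data frame with a `sample_id` first column
#'   and numeric locus columns, or a numeric matrix.
#' @param eps Clip margin, a small positive value below 0.5.
#' @return A tibble with the same shape, entries in `[eps, 1 - eps]`.
#' @export
clip_beta_values <- function(data, eps = 1e-6) {
  if (!is.numeric(eps) || eps <= 0 || eps >= 0.5) {
    abort("`eps` must be a positive number below 0.5.")
  }
  m <- as_beta_matrix(data)
  m[m < eps] <- eps
  m[m > 1 - eps] <- 1 - eps
  beta_tbl(m)
}

#' Drop loci that fail detection p-value quality control
#'
#' Illumina arrays report a per-measurement detection p-value; a large value
#' flags an unreliable probe reading. A locus is excluded when the fraction of
#' samples with detection p-value above `p_cut` strictly exceeds `frac_cut`
#' (with the defaults: p > 0.01 in more than 10% of samples).
#'
#' @param data Beta-value table (data frame with `sample_id` first column, or
#'   matrix).
#' @param pvalues Detection p-value table of the same shape and ids as `data`.
#' @param p_cut Detection p-value threshold above which a reading counts as
#'   failed.
#' @param frac_cut Tolerated fraction of failed samples per locus; exclusion
#'   triggers strictly above it.
#' @return A tibble containing only the retained loci, original order kept.
#' @export
filter_detection_pvalues <- function(data, pvalues, p_cut = 0.01,
                                     frac_cut = 0.10) {
  m <- as_beta_matrix(data)
  p <- as_beta_matrix(pvalues, range = c(0, 1), what = "detection p-value")
  if (!identical(dim(m), dim(p))) {
    abort(paste0("`pvalues` is ", nrow(p), " x ", ncol(p),
                 " but `data` is ", nrow(m), " x ", ncol(m), "."))
  }
  if (!identical(rownames(m), rownames(p)) ||
      !identical(colnames(m), colnames(p))) {
    abort("`pvalues` must carry the same sample and locus ids as `data`.")
  }
  failed_frac <- colMeans(p > p_cut)
  beta_tbl(m[, failed_frac <= frac_cut, drop = FALSE])
}

#' Per-locus variance report
#'
#' Across-sample variance of every locus (unbiased, divisor n - 1), ranked in
#' decreasing order. Useful for inspecting or exporting the variance filter's
#' input.
#'
#' @inheritParams clip_beta_values
#' @return A tibble with columns `locus_id`, `variance`, `rank`, sorted by
#'   decreasing variance; ties keep original column order.
#' @export
locus_variances <- function(data) {
  m <- as_beta_matrix(data, range = c(-Inf, Inf))
  v <- apply(m, 2L, var)
  ord <- order(-v)  # stable: ties by original column order
  tibble::tibble(locus_id = colnames(m)[ord], variance = unname(v[ord]),
                 rank = seq_along(v))
}

#' Keep only the most variable loci
#'
#' With few samples and many loci, most loci barely vary and contribute noise
#' rather than cluster signal. This keeps the `j` loci with the largest
#' across-sample variance, returned in decreasing-variance order.
#'
#' @inheritParams clip_beta_values
#' @param j Number of loci to keep, between 1 and the number of loci.
#' @return A tibble with `sample_id` plus the `j` selected locus columns,
#'   ordered by decreasing variance (ties by original column order).
#' @export
select_variable_loci <- function(data, j) {
  m <- as_beta_matrix(data, range = c(-Inf, Inf))
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > ncol(m) ||
      j != round(j)) {
    abort(paste0("`j` must be a whole number between 1 and ", ncol(m),
                 " (the number of loci)."))
  }
  keep <- locus_variances(data)$locus_id[seq_len(j)]
  beta_tbl(m[, keep, drop = FALSE])
}
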