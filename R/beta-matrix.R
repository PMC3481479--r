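# Internal representation: a numeric samples x loci matrix with rownames =
# sample ids and colnames = locus ids. The user-facing representation is a
# tibble whose first column (`sample_id`) holds sample identifiers and whose
# remaining columns are numeric loci.

#' Convert a beta-value table to the internal samples-by-loci matrix
#'
#' Accepts either a numeric matrix (rownames as sample ids) or a data frame
#' whose first column holds sample identifiers and whose remaining columns are
#' numeric beta values. Used internally by every data-frame-first function.
#'
#' @param data A data frame or numeric matrix of beta values.
#' @param range Allowed closed range for entries; entries outside it are an
#'   error. Use `c(0, 1)` for raw beta values, `c(-Inf, Inf)` to skip.
#' @param what Noun used in error messages (e.g. "beta value").
#' @return A numeric matrix with unique rownames and colnames.
#' @keywords internal
as_beta_matrix <- function(data, range = c(0, 1), what = "beta value") {
  if (is.matrix(data)) {
    m <- data
    if (is.null(rownames(m))) rownames(m) <- paste0("sample_", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("locus_", seq_len(ncol(m)))
  } else if (is.data.frame(data)) {
    if (ncol(data) < 2L) {
      abort("`data` must have a sample-id column plus at least one locus column.")
    }
    ids <- as.character(data[[1L]])
    num <- data[, -1L, drop = FALSE]
    bad <- names(num)[!vapply(num, is.numeric, logical(1))]
    if (length(bad) > 0L) {
      abort(paste0("Non-numeric locus column(s): ", toString(head(bad, 5L)), "."))
    }
    m <- as.matrix(num)
    rownames(m) <- ids
  } else {
    abort("`data` must be a data frame or a numeric matrix.")
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) abort("Duplicate sample ids in `data`.")
  if (anyDuplicated(colnames(m))) abort("Duplicate locus ids in `data`.")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    abort(paste0("Missing value at sample '", rownames(m)[idx[1L]],
                 "', locus '", colnames(m)[idx[2L]],
                 "'; missing values are not supported."))
  }
  if (is.finite(range[1L]) || is.finite(range[2L])) {
    out <- m < range[1L] | m > range[2L]
    if (any(out)) {
      idx <- which(out, arr.ind = TRUE)[1L, ]
      abort(paste0(
        "Invalid ", what, " ", format(m[idx[1L], idx[2L]]), " at sample '",
        rownames(m)[idx[1L]], "', locus '", colnames(m)[idx[2L]],
        "': must lie in [", range[1L], ", ", range[2L], "]."))
    }
  }
  m
}

# Matrix back to the tidy representation.
beta_tbl <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
}

# Strict open-interval check used before likelihood evaluation.
check_open_unit <- function(m) {
  if (any(m <= 0 | m >= 1)) {
    abort(paste0(
      "Beta values must lie strictly inside (0, 1) before model fitting; ",
      "apply clip_beta_values() first."))
  }
  invisible(m)
}
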