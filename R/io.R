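#' Read a beta-value (or detection p-value) matrix from delimited text
#'
#' Reads a rectangular delimited file with a header row and an identifier
#' first column. The delimiter follows the extension: `.csv` is comma, any
#' other extension tab. Array exports conventionally store loci in rows;
#' `orientation = "loci"` transposes them to the internal samples-by-loci
#' layout.
#'
#' @param path Path to the file.
#' @param orientation `"samples"` when rows are samples, `"loci"` when rows
#'   are loci.
#' @param range Allowed value range; defaults to the unit interval. Entries
#'   outside it raise an error naming the offending cell.
#' @return A tibble with `sample_id` plus one numeric column per locus.
#' @export
read_beta_matrix <- function(path, orientation = c("samples", "loci"),
                             range = c(0, 1)) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE, progress = FALSE,
               name_repair = "minimal")
  if (ncol(df) < 2L) abort("Expected an id column plus at least one data column.")
  ids <- as.character(df[[1L]])
  for (j in seq(2L, ncol(df))) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))[1L]
      abort(paste0("Non-numeric value '", df[[j]][bad], "' in column '",
                   names(df)[j], "', row ", bad, " of ", path, "."))
    }
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "loci") m <- t(m)
  beta_tbl(as_beta_matrix(m, range = range,
                          what = paste0("value in ", basename(path))))
}

#' Write a beta-value table to delimited text
#'
#' @param data Beta-value table (tibble with `sample_id`, or matrix).
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(data, path) {
  tbl <- beta_tbl(as_beta_matrix(data, range = c(-Inf, Inf)))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tbl, path)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}

#' Write the full result set of a fit to a directory
#'
#' Writes the point-estimate assignments (TSV), the kept-iteration trace
#' (CSV: iteration, k, tau, log_joint), the posterior co-clustering matrix
#' (CSV), an optional BCubed evaluation against reference labels (TSV), and a
#' run manifest (JSON) echoing the configuration, seed, package version and
#' timestamps.
#'
#' @param fit A `dpbmm` fit.
#' @param dir Output directory (created if needed).
#' @param truth Optional reference label vector aligned to the fit's samples.
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_dpbmm_results <- function(fit, dir, truth = NULL, prefix = "dpbmm") {
  stopifnot(inherits(fit, "dpbmm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L) {
    abort(paste0("Output directory is not writable: ", dir))
  }
  paths <- c(
    assignments = file.path(dir, paste0(prefix, "_assignments.tsv")),
    trace = file.path(dir, paste0(prefix, "_trace.csv")),
    coclustering = file.path(dir, paste0(prefix, "_coclustering.csv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  readr::write_tsv(fit$assignments, paths[["assignments"]])
  readr::write_csv(fit$trace, paths[["trace"]])
  cc <- tibble::as_tibble(as.data.frame(fit$coclustering))
  names(cc) <- fit$sample_ids
  readr::write_csv(dplyr::bind_cols(tibble::tibble(sample_id = fit$sample_ids),
                                    cc), paths[["coclustering"]])
  if (!is.null(truth)) {
    paths <- c(paths,
               evaluation = file.path(dir, paste0(prefix, "_evaluation.tsv")))
    readr::write_tsv(
      evaluate_clustering(truth = truth,
                          predicted = fit$assignments$cluster),
      paths[["evaluation"]])
  }
  manifest <- list(
    package = "dpbmm",
    version = as.character(utils::packageVersion("dpbmm")),
    config = fit$config,
    n_samples = fit$n, n_loci = fit$n_loci,
    k_hat = fit$k_hat,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
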