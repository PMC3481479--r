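#' Pairwise correctness of two partitions
#'
#' For samples `i` and `j`, the relation between a reference partition `truth`
#' and a candidate partition `predicted` is correct (1) when the two samples
#' are together in both partitions or apart in both, and incorrect (0)
#' otherwise.
#'
#' @param truth,predicted Label vectors of equal length; values are arbitrary
#'   cluster identifiers.
#' @param i,j Sample indices.
#' @return 0 or 1.
#' @export
bcubed_correctness <- function(truth, predicted, i, j) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  n <- length(truth)
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) {
    abort(paste0("Indices must lie in 1..", n, "."))
  }
  as.integer((truth[i] == truth[j]) == (predicted[i] == predicted[j]))
}

#' BCubed overall precision and recall
#'
#' Recall is the average over samples of the average correctness across all
#' samples sharing the same *true* cluster (self pair included); precision is
#' the same with the roles of the two partitions swapped, averaging over
#' samples sharing the same *predicted* cluster. Both are label-permutation
#' invariant and lie in (0, 1].
#'
#' @inheritParams bcubed_correctness
#' @return A named list with elements `precision` and `recall`.
#' @export
bcubed_precision_recall <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  if (length(truth) == 0L) abort("Label vectors must be non-empty.")
  same_c <- outer(truth, truth, "==")
  same_s <- outer(predicted, predicted, "==")
  correct <- same_c == same_s
  recall <- mean(rowSums(correct & same_c) / rowSums(same_c))
  precision <- mean(rowSums(correct & same_s) / rowSums(same_s))
  list(precision = precision, recall = recall)
}

#' Harmonic mean of precision and recall
#'
#' The F measure combining BCubed precision and recall with equal weight:
#' \eqn{F = 1 / (0.5/P + 0.5/R)}. If either input is zero, F is defined as the
#' limit 0 and a warning is raised.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The harmonic mean.
#' @export
f_measure <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    abort("`precision` and `recall` must lie in [0, 1].")
  }
  out <- ifelse(precision == 0 | recall == 0, 0,
                1 / (0.5 / precision + 0.5 / recall))
  if (any(precision == 0 | recall == 0)) {
    warn("Zero precision or recall: F reported as its limit, 0.")
  }
  out
}

#' Evaluate a clustering against reference labels
#'
#' One-stop BCubed evaluation: overall precision, recall, and F measure of a
#' predicted partition against a reference partition, plus the cluster counts
#' of both.
#'
#' @param data A data frame holding the two label columns, or `NULL` to pass
#'   label vectors directly via `truth` and `predicted`.
#' @param truth,predicted Column names (when `data` is given) or label vectors.
#' @return A one-row tibble: `precision`, `recall`, `f_measure`, `k_true`,
#'   `k_pred`, `n`.
#' @examples
#' evaluate_clustering(truth = c(1, 1, 2, 2), predicted = c(1, 1, 1, 1))
#' @export
evaluate_clustering <- function(data = NULL, truth, predicted) {
  if (!is.null(data)) {
    truth <- data[[rlang::as_name(rlang::enquo(truth))]]
    predicted <- data[[rlang::as_name(rlang::enquo(predicted))]]
  }
  pr <- bcubed_precision_recall(truth, predicted)
  tibble::tibble(
    precision = pr$precision,
    recall = pr$recall,
    f_measure = f_measure(pr$precision, pr$recall),
    k_true = length(unique(truth)),
    k_pred = length(unique(predicted)),
    n = length(truth)
  )
}

#' Match estimated clusters to reference clusters by majority overlap
#'
#' For each reference cluster, finds the estimated cluster containing the
#' largest number of its members, and reports that cluster's total size and
#' sample fraction. Useful for comparing estimated mixing proportions to
#' known ones without solving a full assignment problem.
#'
#' @inheritParams bcubed_correctness
#' @return A tibble with one row per reference cluster: `true_cluster`,
#'   `matched_cluster`, `overlap` (shared samples), `matched_size`, and
#'   `matched_fraction` (matched cluster size over n).
#' @export
match_clusters <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  n <- length(truth)
  tab <- table(truth, predicted)
  pred_sizes <- table(predicted)
  purrr::map_dfr(rownames(tab), function(tc) {
    j <- which.max(tab[tc, ])
    tibble::tibble(
      true_cluster = tc,
      matched_cluster = colnames(tab)[j],
      overlap = as.integer(tab[tc, j]),
      matched_size = as.integer(pred_sizes[colnames(tab)[j]]),
      matched_fraction = as.integer(pred_sizes[colnames(tab)[j]]) / n)
  })
}
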