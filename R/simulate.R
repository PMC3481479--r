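#' Simulate methylation profiles from a finite beta mixture
#'
#' Draws cluster labels from fixed mixing proportions, then, for each cluster
#' and locus, draws unconstrained shape parameters \eqn{L_\alpha, L_\beta \sim
#' N(0, \sigma_k^2)} with a per-cluster spread \eqn{\sigma_k}, maps them to
#' beta shapes through `transform_beta_params()`, and samples every beta value
#' from its cluster's per-locus beta distribution. Larger `l_sigma` spreads
#' the shape parameters further from (1, 1) and makes clusters easier to
#' separate.
#'
#' The defaults reproduce a four-cluster benchmark: 100 samples, 200 loci,
#' mixing proportions (0.2, 0.3, 0.2, 0.3), per-cluster spreads
#' (1.0, 1.5, 2.0, 2.5).
#'
#' @param n Number of samples.
#' @param L Number of loci.
#' @param proportions Mixing proportions, positive and summing to 1; their
#'   length sets the number of clusters.
#' @param l_sigma Per-cluster standard deviation of the unconstrained shape
#'   parameters; recycled to the number of clusters.
#' @param seed Optional integer seed for reproducibility.
#' @return A `dpbmm_sim` object: a list with `data` (tibble, `sample_id` plus
#'   locus columns), `labels` (tibble `sample_id`, `cluster`), `components`
#'   (tibble of true per-cluster, per-locus shape parameters), `proportions`,
#'   and `params` (the generator settings, seed included).
#' @examples
#' sim <- simulate_beta_mixture(n = 20, L = 10, seed = 1)
#' dplyr::count(sim$labels, cluster)
#' @export
simulate_beta_mixture <- function(n = 100, L = 200,
                                  proportions = c(0.2, 0.3, 0.2, 0.3),
                                  l_sigma = c(1.0, 1.5, 2.0, 2.5),
                                  seed = NULL) {
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must be positive and sum to 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- length(proportions)
  l_sigma <- rep_len(l_sigma, K)
  labels <- sample.int(K, n, replace = TRUE, prob = proportions)
  la <- matrix(rnorm(K * L, 0, l_sigma), nrow = K, ncol = L)
  lb <- matrix(rnorm(K * L, 0, l_sigma), nrow = K, ncol = L)
  alpha <- exp(abs(la))
  beta <- exp(abs(lb))
  x <- matrix(rbeta(n * L, alpha[labels, ], beta[labels, ]), nrow = n, ncol = L)
  finish_simulation(
    x, labels,
    components = tibble::tibble(
      cluster = rep(seq_len(K), L),
      locus_id = rep(paste0("locus_", seq_len(L)), each = K),
      l_alpha = as.vector(la), l_beta = as.vector(lb),
      alpha = as.vector(alpha), beta = as.vector(beta)),
    proportions = proportions,
    params = list(generator = "beta_mixture", n = n, L = L,
                  proportions = proportions, l_sigma = l_sigma, seed = seed))
}

#' Simulate class-structured methylation profiles with bimodal loci
#'
#' Emulates the bimodal character of real methylation panels: every locus is
#' either hypomethylated (beta values near `hypo_mean`) or hypermethylated
#' (near `hyper_mean`). Most loci share one methylation state across all
#' classes and carry no cluster signal; a fraction `p_variable` of loci are
#' class-variable, each class tossing its own fair coin between the two
#' states. Class-variable loci have large across-sample variance, so they are
#' the ones a variance filter retains.
#'
#' Within a state, beta values are drawn from a beta distribution with mean
#' equal to the state mean and concentration (alpha + beta) equal to
#' `concentration`. The state means control class separation; the defaults
#' (0.2 and 0.8 at concentration 10) give clearly bimodal but overlapping
#' values, in line with array data.
#'
#' @param n Number of subjects.
#' @param L Number of loci.
#' @param K Number of classes.
#' @param proportions Class proportions; default equiprobable.
#' @param p_variable Fraction of loci whose state differs by class.
#' @param hypo_mean,hyper_mean State means of the hypo- and hypermethylated
#'   beta distributions.
#' @param concentration Sum alpha + beta of each state's beta distribution;
#'   larger values concentrate beta values around the state mean.
#' @param seed Optional integer seed.
#' @return A `dpbmm_sim` object (see [simulate_beta_mixture()]).
#' @export
simulate_methylation_classes <- function(n = 100, L = 1413, K = 5,
                                         proportions = rep(1 / K, K),
                                         p_variable = 0.1,
                                         hypo_mean = 0.2, hyper_mean = 0.8,
                                         concentration = 10,
                                         seed = NULL) {
  if (any(proportions <= 0) || abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must be positive and sum to 1.")
  }
  if (length(proportions) != K) abort("`proportions` must have length `K`.")
  if (hypo_mean <= 0 || hyper_mean >= 1 || hypo_mean >= hyper_mean) {
    abort("Require 0 < hypo_mean < hyper_mean < 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- sample.int(K, n, replace = TRUE, prob = proportions)
  variable <- runif(L) < p_variable
  # state[k, l]: TRUE = hypermethylated for class k at locus l
  shared_state <- runif(L) < 0.5
  state <- matrix(rep(shared_state, each = K), nrow = K, ncol = L)
  n_var <- sum(variable)
  if (n_var > 0L) {
    state[, variable] <- matrix(runif(K * n_var) < 0.5, nrow = K)
  }
  mean_mat <- ifelse(state, hyper_mean, hypo_mean)
  alpha <- mean_mat * concentration
  beta <- (1 - mean_mat) * concentration
  x <- matrix(rbeta(n * L, alpha[labels, ], beta[labels, ]), nrow = n, ncol = L)
  finish_simulation(
    x, labels,
    components = tibble::tibble(
      cluster = rep(seq_len(K), L),
      locus_id = rep(paste0("locus_", seq_len(L)), each = K),
      alpha = as.vector(alpha), beta = as.vector(beta),
      hypermethylated = as.vector(state),
      class_variable = rep(variable, each = K)),
    proportions = proportions,
    params = list(generator = "methylation_classes", n = n, L = L, K = K,
                  proportions = proportions, p_variable = p_variable,
                  hypo_mean = hypo_mean, hyper_mean = hyper_mean,
                  concentration = concentration, seed = seed))
}

#' Five-class methylation benchmark
#'
#' A class-structured benchmark with 100 subjects, 1413 loci, and five
#' equiprobable classes, built on [simulate_methylation_classes()].
#'
#' @inheritParams simulate_methylation_classes
#' @param ... Further arguments passed to [simulate_methylation_classes()].
#' @return A `dpbmm_sim` object.
#' @export
simulate_five_class_benchmark <- function(n = 100, L = 1413, seed = NULL, ...) {
  simulate_methylation_classes(n = n, L = L, K = 5, seed = seed, ...)
}

#' Four-class methylation benchmark
#'
#' A class-structured benchmark with 100 subjects and four equiprobable
#' classes over a smaller locus panel, built on
#' [simulate_methylation_classes()].
#'
#' @inheritParams simulate_methylation_classes
#' @param ... Further arguments passed to [simulate_methylation_classes()].
#' @return A `dpbmm_sim` object.
#' @export
simulate_four_class_benchmark <- function(n = 100, L = 100, seed = NULL, ...) {
  simulate_methylation_classes(n = n, L = L, K = 4, seed = seed, ...)
}

finish_simulation <- function(x, labels, components, proportions, params) {
  # rbeta can hit the boundaries in floating point for extreme shapes
  eps <- 1e-12
  x[x <= 0] <- eps
  x[x >= 1] <- 1 - eps
  rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  colnames(x) <- paste0("locus_", seq_len(ncol(x)))
  structure(
    list(
      data = beta_tbl(x),
      labels = tibble::tibble(sample_id = rownames(x), cluster = labels),
      components = components,
      proportions = proportions,
      params = params),
    class = "dpbmm_sim")
}

#' @export
print.dpbmm_sim <- function(x, ...) {
  n <- nrow(x$data)
  L <- ncol(x$data) - 1L
  K <- length(x$proportions)
  cat("Simulated methylation dataset (", x$params$generator, ")\n", sep = "")
  cat("  ", n, " samples x ", L, " loci, ", K, " clusters\n", sep = "")
  cat("  true proportions: ", paste(signif(x$proportions, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the beta-value matrix as TSV, the true labels as a sidecar TSV
#' (`sample_id`, `true_cluster`), and the generator settings (seed included)
#' as JSON.
#'
#' @param sim A `dpbmm_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "dpbmm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    data = file.path(dir, paste0(prefix, "_beta_values.tsv")),
    labels = file.path(dir, paste0(prefix, "_true_labels.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.json")))
  readr::write_tsv(sim$data, paths[["data"]])
  readr::write_tsv(
    dplyr::rename(sim$labels, true_cluster = "cluster"), paths[["labels"]])
  jsonlite::write_json(sim$params, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
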