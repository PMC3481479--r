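#' Cluster methylation profiles with a Dirichlet process beta mixture
#'
#' Fits an infinite beta mixture to a samples-by-loci table of methylation
#' beta values by Gibbs sampling and returns a point-estimate clustering plus
#' the full posterior trace. Each cluster models every locus with its own beta
#' distribution; the Dirichlet process prior lets the number of clusters be
#' learned from the data rather than fixed in advance.
#'
#' The sampler iterates four blocks: (1) a "no-gaps" label update for every
#' sample, in which an existing cluster is chosen with weight proportional to
#' its size times the sample's likelihood under it, and a brand-new cluster
#' (parameters drawn from the base measure) with weight proportional to
#' `tau` over the number of candidate clusters; (2) random-walk Metropolis
#' updates of each cluster's per-locus shape parameters on an unconstrained
#' log scale; (3) a Dirichlet draw of the mixing proportions; (4) an
#' auxiliary-variable gamma update of the concentration `tau`.
#'
#' The point estimate reported is the kept iteration with the highest log
#' joint density among iterations whose cluster count equals the posterior
#' mode of K (ties in the mode broken toward fewer clusters).
#'
#' @param data Beta-value table: a data frame with a `sample_id` first column
#'   and numeric locus columns, or a numeric matrix. Values are clipped into
#'   the open unit interval with `clip_eps` before fitting.
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before recording.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param init_k Number of clusters used to scatter the initial labels.
#' @param sigma_alpha,sigma_beta Base-measure standard deviations of the
#'   unconstrained shape parameters.
#' @param mh_step Random-walk proposal standard deviation for the shape
#'   parameter updates.
#' @param mh_inner Metropolis proposals per locus per sweep.
#' @param mh_adapt Adapt `mh_step` toward ~37% acceptance during burn-in only.
#' @param tau_a,tau_b Shape and rate of the gamma prior on the concentration
#'   parameter.
#' @param clip_eps Boundary clip applied to the data before fitting.
#' @param seed Optional integer seed; a seeded fit is fully reproducible.
#' @param verbose Print progress every 100 iterations.
#' @return A `dpbmm` object with components `assignments` (tibble `sample_id`,
#'   `cluster`), `k_hat`, `proportions` (tibble `cluster`, `proportion`),
#'   `trace` (tibble `iteration`, `k`, `tau`, `log_joint`), `label_trace`
#'   (kept-iterations x samples matrix), `coclustering` (posterior co-clustering
#'   proportion matrix), `mh_acceptance`, and `config`.
#' @examples
#' sim <- simulate_beta_mixture(n = 30, L = 20, proportions = c(0.5, 0.5),
#'                              l_sigma = c(2, 2), seed = 1)
#' fit <- dpbmm(sim$data, n_iter = 200, burn_in = 50, seed = 1)
#' glance(fit)
#' @export
dpbmm <- function(data, n_iter = 2000, burn_in = 300, thin = 1, init_k = 1,
                  sigma_alpha = 1, sigma_beta = 1,
                  mh_step = 0.3, mh_inner = 2, mh_adapt = FALSE,
                  tau_a = 1, tau_b = 1,
                  clip_eps = 1e-6, seed = NULL, verbose = FALSE) {
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")
  m <- as_beta_matrix(clip_beta_values(data, eps = clip_eps))
  if (nrow(m) < 2L) abort("Need at least two samples to cluster.")
  if (!is.null(seed)) set.seed(seed)
  cfg <- default_config(
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), init_k = as.integer(init_k),
    sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
    mh_step = mh_step, mh_inner = as.integer(mh_inner), mh_adapt = mh_adapt,
    tau_a = tau_a, tau_b = tau_b, verbose = verbose)
  dat <- make_data_cache(m)
  trace <- run_gibbs(dat, cfg)
  summ <- summarize_posterior(trace)
  structure(
    list(
      assignments = tibble::tibble(sample_id = rownames(m),
                                   cluster = summ$labels),
      k_hat = summ$k_hat,
      proportions = tibble::tibble(cluster = seq_len(summ$k_hat),
                                   proportion = summ$pi_hat),
      trace = tibble::tibble(iteration = trace$iterations,
                             k = trace$k, tau = trace$tau,
                             log_joint = trace$log_joint),
      label_trace = trace$labels,
      coclustering = trace$coclustering / trace$n_kept,
      mh_acceptance = trace$mh_acceptance,
      n = nrow(m), n_loci = ncol(m),
      sample_ids = rownames(m), locus_ids = colnames(m),
      config = c(cfg[c("n_iter", "burn_in", "thin", "init_k", "sigma_alpha",
                       "sigma_beta", "mh_step", "mh_inner", "mh_adapt",
                       "tau_a", "tau_b")],
                 list(clip_eps = clip_eps, seed = seed)),
      call = match.call()),
    class = "dpbmm")
}

#' @export
print.dpbmm <- function(x, ...) {
  cat("Dirichlet process beta mixture fit\n")
  cat("  ", x$n, " samples x ", x$n_loci, " loci, ",
      nrow(x$trace), " kept iterations\n", sep = "")
  cat("  estimated clusters: ", x$k_hat, "\n", sep = "")
  cat("  estimated proportions: ",
      paste(sprintf("%.2f", x$proportions$proportion), collapse = ", "),
      "\n", sep = "")
  cat("  posterior mean tau: ", sprintf("%.3f", mean(x$trace$tau)),
      "; MH acceptance: ", sprintf("%.2f", x$mh_acceptance), "\n", sep = "")
  invisible(x)
}

#' @describeIn dpbmm Per-sample cluster assignments as a tibble, with each
#'   sample's posterior co-clustering confidence (mean co-assignment
#'   proportion with the other members of its cluster).
#' @param x,object A `dpbmm` fit.
#' @param ... Unused.
#' @export
tidy.dpbmm <- function(x, ...) {
  conf <- vapply(seq_len(x$n), function(i) {
    mates <- which(x$assignments$cluster == x$assignments$cluster[i])
    mean(x$coclustering[i, mates])
  }, numeric(1))
  dplyr::mutate(x$assignments, confidence = conf)
}

#' @describeIn dpbmm One-row model summary: sample and locus counts, estimated
#'   K, posterior mean and dispersion of K and tau, best log joint density,
#'   and Metropolis acceptance rate.
#' @export
glance.dpbmm <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_loci = x$n_loci, k_hat = x$k_hat,
    k_mean = mean(x$trace$k), k_sd = stats::sd(x$trace$k),
    tau_mean = mean(x$trace$tau),
    log_joint_best = max(x$trace$log_joint),
    mh_acceptance = x$mh_acceptance,
    n_kept = nrow(x$trace))
}

#' Plot the trace of the number of clusters
#'
#' Kept-iteration trace of K, the standard convergence diagnostic for a
#' Dirichlet process mixture run: after burn-in the trace should settle
#' around the posterior mode.
#'
#' @param object A `dpbmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpbmm <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iteration, .data$k)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::scale_y_continuous(breaks = function(lims)
      unique(floor(lims[1]):ceiling(lims[2]))) +
    ggplot2::labs(x = "Gibbs iteration", y = "Number of clusters K",
                  title = "Posterior trace of the cluster count") +
    ggplot2::theme_minimal()
}

#' Plot the posterior co-clustering matrix
#'
#' Heatmap of the proportion of kept iterations in which each pair of samples
#' shared a cluster, with samples ordered by their point-estimate cluster.
#' Crisp blocks indicate a stable partition.
#'
#' @param fit A `dpbmm` fit.
#' @return A ggplot object.
#' @export
plot_coclustering <- function(fit) {
  stopifnot(inherits(fit, "dpbmm"))
  ord <- order(fit$assignments$cluster)
  cc <- fit$coclustering[ord, ord]
  df <- tidyr::expand_grid(row = seq_len(nrow(cc)), col = seq_len(ncol(cc)))
  df$value <- cc[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Co-clustering", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Posterior co-clustering (samples ordered by cluster)") +
    ggplot2::theme_minimal()
}
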