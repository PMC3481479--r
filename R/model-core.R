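#' Map unconstrained shape parameters to beta shapes
#'
#' The beta shape parameters of every mixture component are sampled on an
#' unconstrained scale: a locus with unconstrained values \eqn{(L_\alpha,
#' L_\beta)} has shapes \eqn{\alpha = \exp(|L_\alpha|)} and \eqn{\beta =
#' \exp(|L_\beta|)}. The absolute value guarantees \eqn{\alpha \ge 1} and
#' \eqn{\beta \ge 1}, the regime in which beta densities on methylation beta
#' values are unimodal.
#'
#' @param l_alpha,l_beta Numeric vectors of unconstrained values (recycled to a
#'   common length).
#' @return A tibble with columns `alpha` and `beta`, both `>= 1`.
#' @examples
#' transform_beta_params(0, 0)          # alpha = beta = 1
#' transform_beta_params(log(3), log(2))
#' @export
transform_beta_params <- function(l_alpha, l_beta) {
  if (!is.numeric(l_alpha) || !is.numeric(l_beta) ||
      any(!is.finite(l_alpha)) || any(!is.finite(l_beta))) {
    abort("`l_alpha` and `l_beta` must be finite numeric vectors.")
  }
  n <- max(length(l_alpha), length(l_beta))
  tibble::tibble(
    alpha = exp(abs(rep_len(l_alpha, n))),
    beta  = exp(abs(rep_len(l_beta, n)))
  )
}

#' Log density of a beta distribution, evaluated stably
#'
#' Computes \eqn{(\alpha-1)\log x + (\beta-1)\log(1-x) - \log B(\alpha,\beta)}
#' with the log-beta function evaluated through log-gamma, so large shape
#' parameters do not overflow.
#'
#' @param x Numeric vector of values strictly inside (0, 1).
#' @param alpha,beta Beta shape parameters (vectors recycled against `x`).
#' @return Numeric vector of log densities.
#' @export
beta_log_density <- function(x, alpha, beta) {
  if (any(x <= 0 | x >= 1)) {
    abort("`x` must lie strictly inside (0, 1); clip boundary values first.")
  }
  (alpha - 1) * log(x) + (beta - 1) * log1p(-x) - lbeta(alpha, beta)
}

# Component parameters for one cluster: unconstrained (l_alpha, l_beta) per
# locus plus the derived shapes. Stored as plain vectors for speed.
component_params <- function(l_alpha, l_beta) {
  if (length(l_alpha) != length(l_beta)) {
    abort("`l_alpha` and `l_beta` must have equal length.")
  }
  structure(
    list(l_alpha = l_alpha, l_beta = l_beta,
         alpha = exp(abs(l_alpha)), beta = exp(abs(l_beta))),
    class = "dpbmm_component")
}

#' Base measure for component parameters
#'
#' The Dirichlet process base measure G0 is a product of independent zero-mean
#' Gaussians on the unconstrained shape parameters: \eqn{L_\alpha \sim N(0,
#' \sigma_\alpha^2)} and \eqn{L_\beta \sim N(0, \sigma_\beta^2)} at every
#' locus. All prior evaluations in the sampler happen on this unconstrained
#' scale, so no Jacobian terms are needed.
#'
#' @param sigma_alpha,sigma_beta Positive prior standard deviations.
#' @return A `dpbmm_base_measure` list.
#' @export
base_measure <- function(sigma_alpha = 1, sigma_beta = 1) {
  if (!is.numeric(sigma_alpha) || !is.numeric(sigma_beta) ||
      sigma_alpha <= 0 || sigma_beta <= 0) {
    abort("`sigma_alpha` and `sigma_beta` must be positive numbers.")
  }
  structure(list(sigma_alpha = sigma_alpha, sigma_beta = sigma_beta),
            class = "dpbmm_base_measure")
}

#' Log-likelihood of one sample under one mixture component
#'
#' Sums the per-locus beta log densities of a single sample's profile under a
#' component's shape parameters; loci are conditionally independent given the
#' cluster.
#'
#' @param x_row Numeric vector of beta values in (0, 1), one per locus.
#' @param comp A component created by `component_params()`, or any list with
#'   `alpha` and `beta` vectors of the same length as `x_row`.
#' @return A single log-likelihood value.
#' @export
sample_log_likelihood <- function(x_row, comp) {
  if (length(x_row) != length(comp$alpha)) {
    abort(paste0("Profile has ", length(x_row), " loci but the component has ",
                 length(comp$alpha), "."))
  }
  sum(beta_log_density(x_row, comp$alpha, comp$beta))
}

#' Log prior density of a component under the base measure
#'
#' Evaluated on the unconstrained scale: the sum over loci of Gaussian log
#' densities of `l_alpha` under N(0, sigma_alpha^2) and `l_beta` under
#' N(0, sigma_beta^2).
#'
#' @param comp A component created by `component_params()`.
#' @param g0 A base measure created by `base_measure()`.
#' @return A single log prior density.
#' @export
log_prior_g0 <- function(comp, g0) {
  sum(dnorm(comp$l_alpha, 0, g0$sigma_alpha, log = TRUE)) +
    sum(dnorm(comp$l_beta, 0, g0$sigma_beta, log = TRUE))
}

# Draw a fresh component from G0 (unconstrained scale), length L.
draw_component_g0 <- function(L, g0) {
  component_params(rnorm(L, 0, g0$sigma_alpha), rnorm(L, 0, g0$sigma_beta))
}
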