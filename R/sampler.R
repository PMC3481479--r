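# No-gaps Gibbs sampler internals for the Dirichlet process beta mixture.
#
# State layout (plain list, copy-on-modify):
#   s     integer n, cluster labels in 1..K with no gaps (every label occupied)
#   K     number of occupied clusters
#   la,lb K x L matrices of unconstrained shape parameters
#   A,B   K x L matrices of (alpha - 1), (beta - 1) with alpha = exp(|la|)
#   LBrow K x L matrix of lbeta(alpha, beta) per cluster and locus
#   lbs   K vector, rowSums(LBrow)
#   nk    K vector of cluster sizes
#   pi    K vector of mixing proportions (resampled each sweep; kept
#         consistent as a normalized placeholder when K changes mid-sweep)
#   tau   DP concentration
#
# The data cache holds log(x) and log(1 - x) so each likelihood evaluation is
# a dot product; `prior_only = TRUE` zeroes the likelihood everywhere, turning
# the chain into a sampler of the DP prior (used for validation).

make_data_cache <- function(m, prior_only = FALSE) {
  check_open_unit(m)
  list(x = m, lx = log(m), l1x = log1p(-m),
       n = nrow(m), L = ncol(m),
       sample_ids = rownames(m), locus_ids = colnames(m),
       prior_only = prior_only)
}

# Derived per-cluster quantities from unconstrained parameters.
derive_rows <- function(la, lb) {
  alpha <- exp(abs(la))
  beta <- exp(abs(lb))
  LBrow <- matrix(lbeta(alpha, beta), nrow = nrow(la))
  list(A = alpha - 1, B = beta - 1, LBrow = LBrow, lbs = rowSums(LBrow))
}

# n x K matrix of per-sample log-likelihoods under each occupied cluster.
compute_loglik_matrix <- function(state, dat) {
  if (dat$prior_only) return(matrix(0, dat$n, state$K))
  ll <- tcrossprod(dat$lx, state$A) + tcrossprod(dat$l1x, state$B)
  sweep(ll, 2L, state$lbs, "-")
}

# Log-likelihood of one sample under a fresh G0 component.
fresh_component_loglik <- function(i, dat, g0) {
  fresh <- draw_component_g0(dat$L, g0)
  lbeta_sum <- sum(lbeta(fresh$alpha, fresh$beta))
  ll <- if (dat$prior_only) 0 else {
    sum((fresh$alpha - 1) * dat$lx[i, ]) + sum((fresh$beta - 1) * dat$l1x[i, ]) -
      lbeta_sum
  }
  c(fresh, list(lbeta_sum = lbeta_sum, ll = ll))
}

# One independent fresh G0 component per sample, drawn in a batch at the
# start of a label sweep (statistically identical to drawing on demand).
fresh_components_batch <- function(dat, g0) {
  n <- dat$n
  L <- dat$L
  FLA <- matrix(rnorm(n * L, 0, g0$sigma_alpha), n, L)
  FLB <- matrix(rnorm(n * L, 0, g0$sigma_beta), n, L)
  FA <- exp(abs(FLA))
  FB <- exp(abs(FLB))
  lbeta_sum <- rowSums(matrix(lbeta(FA, FB), n, L))
  ll <- if (dat$prior_only) numeric(n) else {
    rowSums((FA - 1) * dat$lx) + rowSums((FB - 1) * dat$l1x) - lbeta_sum
  }
  list(FLA = FLA, FLB = FLB, FA = FA, FB = FB, lbeta_sum = lbeta_sum, ll = ll)
}

sample_log_weights <- function(logw) {
  w <- exp(logw - max(logw))
  sample.int(length(w), 1L, prob = w)
}

# Placeholder proportions after a mid-sweep change in K; replaced by a proper
# Dirichlet draw in the same sweep's proportion step.
placeholder_pi <- function(state) {
  w <- state$nk + state$tau / state$K
  w / sum(w)
}

append_cluster <- function(state, comp) {
  la_new <- comp$l_alpha
  lb_new <- comp$l_beta
  lbeta_new <- lbeta(comp$alpha, comp$beta)
  state$la <- rbind(state$la, la_new)
  state$lb <- rbind(state$lb, lb_new)
  state$A <- rbind(state$A, comp$alpha - 1)
  state$B <- rbind(state$B, comp$beta - 1)
  state$LBrow <- rbind(state$LBrow, lbeta_new)
  state$lbs <- c(state$lbs, sum(lbeta_new))
  state$nk <- c(state$nk, 1L)
  state$K <- state$K + 1L
  state$pi <- placeholder_pi(state)
  state
}

drop_last_cluster <- function(state) {
  K <- state$K
  state$la <- state$la[-K, , drop = FALSE]
  state$lb <- state$lb[-K, , drop = FALSE]
  state$A <- state$A[-K, , drop = FALSE]
  state$B <- state$B[-K, , drop = FALSE]
  state$LBrow <- state$LBrow[-K, , drop = FALSE]
  state$lbs <- state$lbs[-K]
  state$nk <- state$nk[-K]
  state$K <- K - 1L
  state$pi <- placeholder_pi(state)
  state
}

swap_clusters <- function(state, k1, k2) {
  if (k1 == k2) return(state)
  idx <- c(k1, k2)
  rev_idx <- c(k2, k1)
  state$la[idx, ] <- state$la[rev_idx, , drop = FALSE]
  state$lb[idx, ] <- state$lb[rev_idx, , drop = FALSE]
  state$A[idx, ] <- state$A[rev_idx, , drop = FALSE]
  state$B[idx, ] <- state$B[rev_idx, , drop = FALSE]
  state$LBrow[idx, ] <- state$LBrow[rev_idx, , drop = FALSE]
  state$lbs[idx] <- state$lbs[rev_idx]
  state$nk[idx] <- state$nk[rev_idx]
  state$pi[idx] <- state$pi[rev_idx]
  in1 <- state$s == k1
  state$s[state$s == k2] <- k1
  state$s[in1] <- k2
  state
}

# One no-gaps label update for sample i. `LL` is the current n x K
# log-likelihood cache; `fresh` is the sample's pre-drawn G0 candidate (drawn
# on demand when NULL). Returns the updated state and cache.
resample_label_one <- function(state, i, dat, g0, LL, fresh = NULL) {
  si <- state$s[i]
  K <- state$K
  if (state$nk[si] > 1L) {
    # removing i leaves every cluster occupied: candidates are the K occupied
    # clusters (urn weight n_{-i,l}) plus a fresh G0 draw (weight tau/(K+1))
    if (is.null(fresh)) fresh <- fresh_component_loglik(i, dat, g0)
    logw <- log(state$nk - (seq_len(K) == si)) + LL[i, ]
    logw <- c(logw, log(state$tau / (K + 1)) + fresh$ll)
    new_s <- sample_log_weights(logw)
    if (new_s != si) {
      state$nk[si] <- state$nk[si] - 1L
      if (new_s == K + 1L) {
        state <- append_cluster(state, fresh)
        LL <- cbind(LL, if (dat$prior_only) 0 else {
          drop(dat$lx %*% (fresh$alpha - 1) +
                 dat$l1x %*% (fresh$beta - 1)) - fresh$lbeta_sum
        })
      } else {
        state$nk[new_s] <- state$nk[new_s] + 1L
      }
      state$s[i] <- new_s
    }
  } else {
    # singleton: with probability 1 - 1/K leave the label untouched; otherwise
    # relabel the singleton cluster to position K and resample with k_-i = K-1
    if (runif(1) < 1 / K) {
      if (si != K) {
        state <- swap_clusters(state, si, K)
        LL[, c(si, K)] <- LL[, c(K, si)]
      }
      logw <- c(log(state$nk[-K]), log(state$tau / K)) + LL[i, ]
      new_s <- sample_log_weights(logw)
      if (new_s != K) {
        state$s[i] <- new_s
        state$nk[new_s] <- state$nk[new_s] + 1L
        state <- drop_last_cluster(state)
        LL <- LL[, -K, drop = FALSE]
      }
    }
  }
  list(state = state, LL = LL)
}

# Full label sweep (Gibbs step over every sample in order).
resample_labels_sweep <- function(state, dat, g0) {
  LL <- compute_loglik_matrix(state, dat)
  fb <- fresh_components_batch(dat, g0)
  for (i in seq_len(dat$n)) {
    fresh <- list(l_alpha = fb$FLA[i, ], l_beta = fb$FLB[i, ],
                  alpha = fb$FA[i, ], beta = fb$FB[i, ],
                  lbeta_sum = fb$lbeta_sum[i], ll = fb$ll[i])
    upd <- resample_label_one(state, i, dat, g0, LL, fresh)
    state <- upd$state
    LL <- upd$LL
  }
  state
}

# Metropolis-within-Gibbs update of cluster k's shape parameters. The
# posterior factorizes over loci, so each locus takes an independent
# random-walk step on the unconstrained scale; `mh_inner` proposals per locus.
# Returns the state plus acceptance counts.
resample_component <- function(state, k, dat, g0, mh_step, mh_inner) {
  L <- dat$L
  if (dat$prior_only) {
    comp <- draw_component_g0(L, g0)
    state$la[k, ] <- comp$l_alpha
    state$lb[k, ] <- comp$l_beta
    lbeta_k <- lbeta(comp$alpha, comp$beta)
    state$A[k, ] <- comp$alpha - 1
    state$B[k, ] <- comp$beta - 1
    state$LBrow[k, ] <- lbeta_k
    state$lbs[k] <- sum(lbeta_k)
    return(list(state = state, accepted = L * mh_inner, proposed = L * mh_inner))
  }
  idx <- state$s == k
  nk <- sum(idx)
  slx <- colSums(dat$lx[idx, , drop = FALSE])
  sl1x <- colSums(dat$l1x[idx, , drop = FALSE])
  la <- state$la[k, ]
  lb <- state$lb[k, ]
  a <- exp(abs(la))
  b <- exp(abs(lb))
  lbet <- state$LBrow[k, ]
  sa2 <- g0$sigma_alpha^2
  sb2 <- g0$sigma_beta^2
  accepted <- 0L
  for (rep in seq_len(mh_inner)) {
    la_p <- la + rnorm(L, 0, mh_step)
    lb_p <- lb + rnorm(L, 0, mh_step)
    a_p <- exp(abs(la_p))
    b_p <- exp(abs(lb_p))
    lbet_p <- lbeta(a_p, b_p)
    logr <- -0.5 * ((la_p^2 - la^2) / sa2 + (lb_p^2 - lb^2) / sb2) +
      (a_p - a) * slx + (b_p - b) * sl1x - nk * (lbet_p - lbet)
    acc <- log(runif(L)) < logr
    if (any(acc)) {
      la[acc] <- la_p[acc]
      lb[acc] <- lb_p[acc]
      a[acc] <- a_p[acc]
      b[acc] <- b_p[acc]
      lbet[acc] <- lbet_p[acc]
      accepted <- accepted + sum(acc)
    }
  }
  state$la[k, ] <- la
  state$lb[k, ] <- lb
  state$A[k, ] <- a - 1
  state$B[k, ] <- b - 1
  state$LBrow[k, ] <- lbet
  state$lbs[k] <- sum(lbet)
  list(state = state, accepted = accepted, proposed = L * mh_inner)
}

# Dirichlet draw of the mixing proportions: pi ~ Dir(n_1 + tau/K, ...).
resample_pi <- function(state) {
  g <- rgamma(state$K, shape = state$nk + state$tau / state$K, rate = 1)
  state$pi <- g / sum(g)
  state
}

# Auxiliary-variable update of the DP concentration given K occupied
# clusters (Escobar-West): eta ~ Beta(tau + 1, n), then tau from a two-part
# gamma mixture with odds (a + K - 1) : n (b - log eta).
resample_tau <- function(state, n, tau_a, tau_b) {
  eta <- rbeta(1, state$tau + 1, n)
  rate <- tau_b - log(eta)
  odds <- (tau_a + state$K - 1) / (n * rate)
  shape <- tau_a + state$K - as.numeric(runif(1) >= odds / (1 + odds))
  state$tau <- rgamma(1, shape = shape, rate = rate)
  state
}

# Unnormalized log joint density of the current state: data likelihood,
# G0 prior on occupied components, the exchangeable partition probability of
# the labels given tau, and the gamma prior on tau.
log_joint <- function(state, dat, g0, tau_a, tau_b) {
  loglik <- 0
  if (!dat$prior_only) {
    SLX <- rowsum(dat$lx, state$s)
    SL1X <- rowsum(dat$l1x, state$s)
    loglik <- sum(state$A * SLX) + sum(state$B * SL1X) -
      sum(state$nk * state$lbs)
  }
  logprior <- sum(dnorm(state$la, 0, g0$sigma_alpha, log = TRUE)) +
    sum(dnorm(state$lb, 0, g0$sigma_beta, log = TRUE))
  n <- dat$n
  eppf <- state$K * log(state$tau) + sum(lgamma(state$nk)) +
    lgamma(state$tau) - lgamma(state$tau + n)
  eppf + loglik + logprior + dgamma(state$tau, tau_a, tau_b, log = TRUE)
}

# Initial state: labels uniform over init_k clusters (gap-compressed),
# components from G0, tau from its prior, pi from its conditional.
init_state <- function(dat, init_k, g0, tau_a, tau_b) {
  n <- dat$n
  if (init_k < 1L || init_k > n) {
    abort(paste0("`init_k` must lie between 1 and the number of samples (",
                 n, ")."))
  }
  s_raw <- if (init_k == 1L) rep(1L, n) else
    sample.int(init_k, n, replace = TRUE)
  s <- match(s_raw, sort(unique(s_raw)))
  K <- max(s)
  la <- matrix(rnorm(K * dat$L, 0, g0$sigma_alpha), nrow = K)
  lb <- matrix(rnorm(K * dat$L, 0, g0$sigma_beta), nrow = K)
  d <- derive_rows(la, lb)
  state <- list(s = s, K = K, la = la, lb = lb,
                A = d$A, B = d$B, LBrow = d$LBrow, lbs = d$lbs,
                nk = as.integer(tabulate(s, K)),
                pi = rep(1 / K, K),
                tau = rgamma(1, tau_a, tau_b))
  state <- resample_pi(state)
  state
}

check_state <- function(state, n) {
  stopifnot(
    state$K == max(state$s),
    all(tabulate(state$s, state$K) > 0L),
    identical(as.integer(tabulate(state$s, state$K)), as.integer(state$nk)),
    sum(state$nk) == n,
    abs(sum(state$pi) - 1) < 1e-10,
    all(state$pi > 0),
    state$tau > 0,
    nrow(state$la) == state$K)
  invisible(TRUE)
}

# Full Gibbs run over a prepared data cache. Returns the raw trace.
run_gibbs <- function(dat, config, g0 = base_measure(config$sigma_alpha,
                                                     config$sigma_beta)) {
  n_iter <- config$n_iter
  burn_in <- config$burn_in
  thin <- config$thin
  stopifnot(burn_in < n_iter, thin >= 1L)
  state <- init_state(dat, config$init_k, g0, config$tau_a, config$tau_b)
  mh_step <- config$mh_step
  keep_iters <- seq(burn_in + 1L, n_iter, by = thin)
  n_keep <- length(keep_iters)
  trace_k <- integer(n_keep)
  trace_tau <- numeric(n_keep)
  trace_lj <- numeric(n_keep)
  trace_s <- matrix(NA_integer_, n_keep, dat$n)
  cocluster <- matrix(0, dat$n, dat$n)
  kept <- 0L
  acc_total <- 0
  prop_total <- 0
  for (it in seq_len(n_iter)) {
    state <- resample_labels_sweep(state, dat, g0)
    acc_iter <- 0
    prop_iter <- 0
    for (k in seq_len(state$K)) {
      upd <- resample_component(state, k, dat, g0, mh_step, config$mh_inner)
      state <- upd$state
      acc_iter <- acc_iter + upd$accepted
      prop_iter <- prop_iter + upd$proposed
    }
    if (!is.null(config$fix_tau)) state$tau <- config$fix_tau
    state <- resample_pi(state)
    if (is.null(config$fix_tau)) {
      state <- resample_tau(state, dat$n, config$tau_a, config$tau_b)
    }
    if (isTRUE(config$mh_adapt) && it <= burn_in && prop_iter > 0) {
      # Robbins-Monro drift of the proposal scale toward ~37% acceptance,
      # frozen after burn-in so the kept chain targets the exact posterior
      mh_step <- exp(log(mh_step) +
                       it^(-0.6) * (acc_iter / prop_iter - 0.375))
    }
    acc_total <- acc_total + acc_iter
    prop_total <- prop_total + prop_iter
    if (isTRUE(config$check_invariants)) check_state(state, dat$n)
    if (it > burn_in && (it - burn_in - 1L) %% thin == 0L) {
      kept <- kept + 1L
      trace_k[kept] <- state$K
      trace_tau[kept] <- state$tau
      trace_lj[kept] <- log_joint(state, dat, g0, config$tau_a, config$tau_b)
      trace_s[kept, ] <- state$s
      cocluster <- cocluster + outer(state$s, state$s, "==")
    }
    if (isTRUE(config$verbose) && it %% 100L == 0L) {
      inform(sprintf("iteration %d / %d: K = %d, tau = %.3f, MH acc = %.2f",
                     it, n_iter, state$K, state$tau,
                     if (prop_total > 0) acc_total / prop_total else NA_real_))
    }
  }
  list(k = trace_k, tau = trace_tau, log_joint = trace_lj,
       labels = trace_s, coclustering = cocluster, n_kept = kept,
       iterations = keep_iters,
       sample_ids = dat$sample_ids,
       mh_acceptance = if (prop_total > 0) acc_total / prop_total else NA_real_,
       final_state = state)
}

# Point-estimate clustering from a trace: modal K over kept iterations (ties
# toward the smaller K), then the kept iteration with that K maximizing the
# log joint density supplies the label vector.
summarize_posterior <- function(trace) {
  if (is.null(trace$n_kept) || trace$n_kept == 0L) {
    abort("Cannot summarize an empty trace.")
  }
  tab <- table(trace$k)
  ks <- as.integer(names(tab))
  k_hat <- min(ks[tab == max(tab)])
  cand <- which(trace$k == k_hat)
  best <- cand[which.max(trace$log_joint[cand])]
  labels <- trace$labels[best, ]
  pi_hat <- as.numeric(tabulate(labels, k_hat)) / length(labels)
  list(labels = labels, k_hat = k_hat, pi_hat = pi_hat, best_iteration = best)
}

default_config <- function(...) {
  cfg <- list(n_iter = 2000L, burn_in = 300L, thin = 1L, init_k = 1L,
              mh_step = 0.3, mh_inner = 2L, mh_adapt = FALSE,
              tau_a = 1, tau_b = 1, sigma_alpha = 1, sigma_beta = 1,
              fix_tau = NULL, check_invariants = FALSE, verbose = FALSE)
  modifyList(cfg, list(...))
}
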