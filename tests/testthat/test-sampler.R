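# Distributional checks of the individual Gibbs blocks and of the whole
# chain against independent oracles (closed forms, forward simulation,
# numeric integration).

test_that("initial states satisfy the no-gaps invariants", {
  dat <- make_cache(random_beta_tbl(12, 4, seed = 1))
  g0 <- base_measure()

  set.seed(1)
  s1 <- dpbmm:::init_state(dat, 1L, g0, 1, 1)
  expect_equal(s1$s, rep(1L, 12))
  expect_equal(s1$K, 1L)
  dpbmm:::check_state(s1, 12)

  set.seed(2)
  a <- dpbmm:::init_state(dat, 5L, g0, 1, 1)
  set.seed(2)
  b <- dpbmm:::init_state(dat, 5L, g0, 1, 1)
  expect_identical(a, b)

  set.seed(3)
  sn <- dpbmm:::init_state(dat, 12L, g0, 1, 1)
  expect_lte(sn$K, 12L)
  dpbmm:::check_state(sn, 12)
  expect_error(dpbmm:::init_state(dat, 13L, g0, 1, 1), "between")
})

test_that("a lone sample always keeps the only cluster", {
  dat <- make_cache(random_beta_tbl(1, 3, seed = 4))
  g0 <- base_measure()
  set.seed(4)
  state <- dpbmm:::init_state(dat, 1L, g0, 1, 1)
  for (rep in 1:50) {
    state <- dpbmm:::resample_labels_sweep(state, dat, g0)
    expect_equal(state$s, 1L)
    expect_equal(state$K, 1L)
  }
})

test_that("one-step label frequencies match the no-gaps urn weights", {
  # constant likelihood (prior_only): a non-singleton sample moves to cluster
  # l with prob prop. to n_{-i,l}, opens a new one with prob prop. to
  # tau/(K+1)
  dat <- make_cache(random_beta_tbl(10, 2, seed = 5), prior_only = TRUE)
  g0 <- base_measure()
  set.seed(5)
  state <- dpbmm:::init_state(dat, 1L, g0, 1, 1)
  state$s <- rep(c(1L, 2L, 3L), c(5L, 3L, 2L))
  state$K <- 3L
  state$nk <- c(5L, 3L, 2L)
  d <- dpbmm:::derive_rows(matrix(rnorm(6), 3), matrix(rnorm(6), 3))
  state$la <- matrix(rnorm(6), 3); state$lb <- matrix(rnorm(6), 3)
  state[c("A", "B", "LBrow", "lbs")] <- d
  state$pi <- rep(1 / 3, 3)
  state$tau <- 2

  LL <- dpbmm:::compute_loglik_matrix(state, dat)
  n_draws <- 40000
  draws <- integer(n_draws)
  set.seed(6)
  for (r in seq_len(n_draws)) {
    upd <- dpbmm:::resample_label_one(state, 1L, dat, g0, LL)
    draws[r] <- upd$state$s[1L]
  }
  w <- c(4, 3, 2, 2 / 4)  # n_{-1,l} for l=1..3, tau/(K+1)
  p <- w / sum(w)
  freq <- tabulate(draws, 4) / n_draws
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(freq - p) < 3.5 * se))
})

test_that("a vanishing concentration never opens a new cluster", {
  dat <- make_cache(random_beta_tbl(8, 2, seed = 7), prior_only = TRUE)
  g0 <- base_measure()
  set.seed(7)
  state <- dpbmm:::init_state(dat, 2L, g0, 1, 1)
  state$tau <- 1e-12
  for (rep in 1:200) {
    state <- dpbmm:::resample_labels_sweep(state, dat, g0)
    expect_lte(state$K, 2L)
  }
})

test_that("a zero proposal step leaves component parameters unchanged", {
  dat <- make_cache(random_beta_tbl(6, 4, seed = 8))
  g0 <- base_measure()
  set.seed(8)
  state <- dpbmm:::init_state(dat, 1L, g0, 1, 1)
  upd <- dpbmm:::resample_component(state, 1L, dat, g0, mh_step = 0,
                                    mh_inner = 3)
  expect_equal(upd$state$la, state$la)
  expect_equal(upd$state$lb, state$lb)
})

test_that("the component update recovers known beta shapes", {
  # single cluster, single locus, data from Beta(3, 6): the posterior mean of
  # (alpha, beta) over kept Metropolis sweeps should sit near the truth
  set.seed(31)
  x <- rbeta(200, 3, 6)
  dat <- make_cache(make_beta_tbl(matrix(x, ncol = 1)))
  g0 <- base_measure()
  state <- dpbmm:::init_state(dat, 1L, g0, 1, 1)
  n_sweep <- 6000
  keep <- matrix(NA_real_, n_sweep, 2)
  for (it in seq_len(n_sweep)) {
    state <- dpbmm:::resample_component(state, 1L, dat, g0, 0.3, 2)$state
    keep[it, ] <- c(exp(abs(state$la[1, 1])), exp(abs(state$lb[1, 1])))
  }
  post_mean <- colMeans(keep[-(1:1000), ])
  expect_lt(abs(post_mean[1] - 3) / 3, 0.15)
  expect_lt(abs(post_mean[2] - 6) / 6, 0.15)
})

test_that("mixing proportions follow the Dirichlet conditional", {
  state <- list(K = 4L, nk = c(19L, 31L, 19L, 31L), tau = 1)
  set.seed(32)
  draws <- t(replicate(20000, dpbmm:::resample_pi(state)$pi))
  expect_true(all(draws > 0))
  expect_equal(rowSums(draws), rep(1, 20000), tolerance = 1e-10)
  shape <- c(19, 31, 19, 31) + 1 / 4
  expected <- shape / sum(shape)
  v <- expected * (1 - expected) / (sum(shape) + 1)
  se <- sqrt(v / 20000)
  expect_true(all(abs(colMeans(draws) - expected) < 3 * se))

  one <- dpbmm:::resample_pi(list(K = 1L, nk = 10L, tau = 1))
  expect_equal(one$pi, 1)
})

test_that("the concentration update targets its analytic conditional", {
  # p(tau | K, n) prop. to dgamma(tau; a, b) tau^K Gamma(tau)/Gamma(tau + n):
  # iterate the auxiliary-variable update and compare empirical quantiles to
  # the numerically normalized density
  n <- 60; K <- 4L; a <- 1; b <- 1
  state <- list(K = K, tau = 1)
  set.seed(33)
  draws <- numeric(20000)
  for (r in seq_along(draws)) {
    state <- dpbmm:::resample_tau(state, n, a, b)
    draws[r] <- state$tau
  }
  expect_true(all(draws > 0))
  log_dens <- function(t) {
    dgamma(t, a, b, log = TRUE) + K * log(t) + lgamma(t) - lgamma(t + n)
  }
  grid <- seq(1e-4, 30, length.out = 20000)
  dens <- exp(log_dens(grid) - max(log_dens(grid)))
  cdf <- cumsum(dens) / sum(dens)
  q_expected <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), function(p) {
    grid[which.min(abs(cdf - p))]
  }, numeric(1))
  q_observed <- unname(quantile(draws[-(1:500)], c(0.1, 0.25, 0.5, 0.75, 0.9)))
  expect_equal(q_observed, q_expected, tolerance = 0.06)
})

test_that("more occupied clusters pull the concentration upward", {
  set.seed(34)
  means <- vapply(c(1L, 5L, 20L), function(K) {
    state <- list(K = K, tau = 1)
    mean(replicate(10000, {
      state <<- dpbmm:::resample_tau(state, 100, 1, 1)
      state$tau
    }))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("state invariants hold after every sweep of a short run", {
  dat <- make_cache(random_beta_tbl(25, 6, seed = 35))
  set.seed(35)
  cfg <- dpbmm:::default_config(n_iter = 60L, burn_in = 10L, init_k = 5L,
                                check_invariants = TRUE)
  trace <- dpbmm:::run_gibbs(dat, cfg)
  expect_equal(trace$n_kept, 50L)
  # every kept label vector is gap-free with K = max(s)
  for (r in seq_len(trace$n_kept)) {
    s <- trace$labels[r, ]
    expect_equal(trace$k[r], max(s))
    expect_true(all(tabulate(s, max(s)) > 0))
  }
  expect_equal(trace$coclustering, t(trace$coclustering))
  expect_equal(diag(trace$coclustering), rep(50, 25))
})

test_that("point estimates use the modal K, breaking ties toward fewer clusters", {
  trace <- list(k = c(2L, 3L, 3L, 2L), tau = rep(1, 4),
                log_joint = c(-5, -1, -2, -4),
                labels = rbind(c(1L, 1L, 2L), c(1L, 2L, 3L),
                               c(1L, 3L, 2L), c(2L, 2L, 1L)),
                n_kept = 4L)
  s <- dpbmm:::summarize_posterior(trace)
  expect_equal(s$k_hat, 2L)  # tie 2 vs 3 broken down
  expect_equal(s$labels, c(2L, 2L, 1L))  # log_joint -4 beats -5
  expect_equal(s$pi_hat, c(1 / 3, 2 / 3))

  single <- list(k = 2L, tau = 1, log_joint = -1,
                 labels = matrix(c(1L, 2L), 1), n_kept = 1L)
  expect_equal(dpbmm:::summarize_posterior(single)$labels, c(1L, 2L))
  expect_error(dpbmm:::summarize_posterior(list(n_kept = 0L)), "empty")
})

test_that("with the likelihood disabled the chain samples the DP prior", {
  # fixed tau = 1, n = 100: E[K] under the Chinese restaurant process is
  # sum_i 1/i = H_100; check against the chain mean with batch-means SE
  dat <- make_cache(random_beta_tbl(100, 2, seed = 36), prior_only = TRUE)
  set.seed(36)
  cfg <- dpbmm:::default_config(n_iter = 2500L, burn_in = 500L,
                                fix_tau = 1, init_k = 5L)
  trace <- dpbmm:::run_gibbs(dat, cfg)
  h_100 <- sum(1 / (1:100))
  se <- batch_se(trace$k)
  expect_lt(abs(mean(trace$k) - h_100), 3 * se + 1e-9)
})

test_that("the prior-only K distribution matches forward CRP simulation", {
  n <- 20; tau <- 1.5
  dat <- make_cache(random_beta_tbl(n, 2, seed = 37), prior_only = TRUE)
  set.seed(37)
  cfg <- dpbmm:::default_config(n_iter = 6000L, burn_in = 1000L, thin = 5L,
                                fix_tau = tau, init_k = 3L)
  trace <- dpbmm:::run_gibbs(dat, cfg)

  crp_k <- replicate(20000, {
    counts <- integer(0)
    for (i in seq_len(n)) {
      p <- c(counts, tau)
      j <- sample.int(length(p), 1, prob = p)
      if (j > length(counts)) counts <- c(counts, 1L) else
        counts[j] <- counts[j] + 1L
    }
    length(counts)
  })
  bins <- 1:8
  obs <- tabulate(pmin(trace$k, 8L), 8)
  expected_p <- tabulate(pmin(crp_k, 8L), 8) / length(crp_k)
  keep <- expected_p > 0.01
  chi <- suppressWarnings(
    chisq.test(obs[keep], p = expected_p[keep] / sum(expected_p[keep])))
  # thinned chain still autocorrelated; demand only gross agreement
  expect_gt(chi$p.value, 1e-4)
})

test_that("identical seeds give identical traces, different seeds differ", {
  tbl <- random_beta_tbl(15, 8, seed = 38)
  f1 <- dpbmm(tbl, n_iter = 80, burn_in = 20, seed = 99)
  f2 <- dpbmm(tbl, n_iter = 80, burn_in = 20, seed = 99)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$assignments, f2$assignments)
  f3 <- dpbmm(tbl, n_iter = 80, burn_in = 20, seed = 100)
  expect_false(identical(f1$trace, f3$trace))
})
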