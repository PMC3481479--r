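test_that("the beta-mixture generator produces valid, reproducible datasets", {
  sim <- simulate_beta_mixture(n = 40, L = 30, seed = 5)
  m <- as.matrix(sim$data[, -1])
  expect_true(all(m > 0 & m < 1))
  expect_equal(dim(m), c(40L, 30L))
  expect_equal(nrow(sim$labels), 40L)
  expect_true(all(sim$labels$cluster %in% 1:4))

  again <- simulate_beta_mixture(n = 40, L = 30, seed = 5)
  expect_identical(sim$data, again$data)
  other <- simulate_beta_mixture(n = 40, L = 30, seed = 6)
  expect_false(identical(sim$data, other$data))
  expect_error(simulate_beta_mixture(proportions = c(0.5, 0.6)), "sum to 1")
})

test_that("label frequencies follow the mixing proportions", {
  props <- c(0.2, 0.3, 0.2, 0.3)
  counts <- matrix(0, 100, 4)
  for (s in 1:100) {
    sim <- simulate_beta_mixture(n = 100, L = 1, proportions = props, seed = s)
    counts[s, ] <- tabulate(sim$labels$cluster, 4)
  }
  freq <- colMeans(counts) / 100
  se <- sqrt(props * (1 - props) / (100 * 100))
  expect_true(all(abs(freq - props) < 3 * se))
})

test_that("per-cluster, per-locus sample means approach alpha/(alpha+beta)", {
  sim <- simulate_beta_mixture(n = 5000, L = 3, proportions = c(0.5, 0.5),
                               l_sigma = c(1, 2), seed = 8)
  m <- as.matrix(sim$data[, -1])
  for (k in 1:2) {
    rows <- sim$labels$cluster == k
    comp <- sim$components[sim$components$cluster == k, ]
    expected <- comp$alpha / (comp$alpha + comp$beta)
    observed <- colMeans(m[rows, , drop = FALSE])
    # beta sd / sqrt(n_k), per locus
    v <- expected * (1 - expected) / (comp$alpha + comp$beta + 1)
    expect_true(all(abs(observed - expected) < 4 * sqrt(v / sum(rows))))
  }
})

test_that("class-structured profiles are bimodal with equiprobable classes", {
  sim <- simulate_five_class_benchmark(seed = 9)
  m <- as.matrix(sim$data[, -1])
  expect_equal(dim(m), c(100L, 1413L))
  expect_true(all(m > 0 & m < 1))
  expect_equal(length(unique(sim$labels$cluster)), 5L)
  freq <- tabulate(sim$labels$cluster, 5) / 100
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / 100)))
  # hypo/hyper bimodality: most mass away from the middle
  expect_gt(mean(m < 0.4 | m > 0.6), 0.75)

  sim4 <- simulate_four_class_benchmark(seed = 10)
  expect_equal(dim(as.matrix(sim4$data[, -1])), c(100L, 100L))
  expect_equal(length(unique(sim4$labels$cluster)), 4L)
  expect_false(identical(simulate_five_class_benchmark(seed = 1)$data,
                         simulate_five_class_benchmark(seed = 2)$data))
})

test_that("class-variable loci carry the between-class variance", {
  sim <- simulate_methylation_classes(n = 200, L = 400, K = 3, seed = 11)
  m <- as.matrix(sim$data[, -1])
  v <- apply(m, 2, var)
  comp <- sim$components
  variable <- comp$class_variable[!duplicated(comp$locus_id)]
  # states actually differing across the three classes
  split <- tapply(comp$hypermethylated, comp$locus_id, function(s) {
    length(unique(s)) > 1
  })[unique(comp$locus_id)]
  expect_true(all(split[!variable] == FALSE))
  expect_gt(mean(v[split]), 5 * mean(v[!split]))
})

test_that("better separated components never cluster worse (median F)", {
  med_f <- vapply(c(0.5, 1.5, 2.5), function(sig) {
    f <- vapply(1:3, function(s) {
      sim <- simulate_beta_mixture(n = 60, L = 60,
                                   proportions = c(0.5, 0.5),
                                   l_sigma = c(sig, sig), seed = 100 + s)
      fit <- dpbmm(sim$data, n_iter = 300, burn_in = 100, seed = s)
      evaluate_clustering(truth = sim$labels$cluster,
                          predicted = fit$assignments$cluster)$f_measure
    }, numeric(1))
    median(f)
  }, numeric(1))
  expect_true(all(diff(med_f) >= 0))
})
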