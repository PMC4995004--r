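two_pop_data <- function(n = 60, genes = 3, seed = 1) {
  withr::with_seed(seed, dplyr::bind_rows(
    population_tibble(0.5, 0.5, 100, n, pop = "A", genes = genes),
    population_tibble(4, 1, 20, n, pop = "B", genes = genes)))
}

test_that("cluster log-likelihood is additive over genes and matches Eq-1 sums", {
  tab <- small_table()
  params <- tibble::tibble(gene = c("g1", "g2", "g3"),
                           k_on = c(1, 0.4, 3), k_off = c(2, 0.8, 1.2),
                           k_t = c(50, 120, 30))
  cell <- c(g1 = 4L, g2 = 0L, g3 = 12L)
  total <- cluster_log_likelihood(cell, params, tab)
  singles <- vapply(1:3, function(g) {
    cluster_log_likelihood(cell[g], params[g, ], tab)
  }, numeric(1))
  expect_equal(total, sum(singles), tolerance = 1e-12)
  direct <- sum(vapply(1:3, function(g) {
    telegraph_log_pmf(cell[[g]], params$k_on[g], params$k_off[g],
                      params$k_t[g])
  }, numeric(1)))
  expect_equal(total, direct, tolerance = 1e-9)
  t0 <- build_lookup_table(grid_spec(1, 1, c(0, 50), x_max = 30))
  expect_identical(
    cluster_log_likelihood(c(g1 = 0L),
                           tibble::tibble(gene = "g1", k_on = 1, k_off = 1,
                                          k_t = 0), t0), 0)
})

test_that("assignment probabilities anneal from softmax to hard argmax", {
  expect_equal(assignment_probabilities(c(-10, -10), tau = 10, t = 0),
               c(0.5, 0.5))
  p <- assignment_probabilities(c(-10, -11), tau = 10, t = 0)
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(p, c(0.7311, 0.2689), tolerance = 1e-4)
  p3 <- assignment_probabilities(c(-10, -11), tau = 10, t = 3)
  expect_gte(p3[1], 1 - 1e-300)
  expect_warning(pu <- assignment_probabilities(c(-Inf, -Inf, -Inf), 10, 1),
                 "uniform")
  expect_equal(pu, rep(1 / 3, 3))
  expect_error(assignment_probabilities(c(-1, -2), tau = 0.5, t = 1))
})

test_that("single runs usually recover two well-separated populations", {
  tab <- small_table()
  d <- two_pop_data(seed = 14)
  truth <- rep(1:2, each = 60)
  rands <- vapply(1:12, function(s) {
    corrected_rand(sabec_single_run(d, k = 2, table = tab, tau = 2, seed = s),
                   truth)
  }, numeric(1))
  expect_gte(mean(rands >= 0.8), 0.75)
  expect_gte(mean(rands), 0.8)
})

test_that("k = 1 collapses to a single cluster after one iteration", {
  tab <- small_table()
  lab <- sabec_single_run(two_pop_data(seed = 2), k = 1, table = tab, seed = 1)
  expect_true(all(lab == 1))
  expect_equal(attr(lab, "iterations"), 1L)
})

test_that("duplicated cells co-cluster", {
  tab <- small_table()
  d <- two_pop_data(n = 30, seed = 3)
  d2 <- d
  d2$cell <- paste0(d2$cell, "_dup")
  both <- dplyr::bind_rows(d, d2)
  hits <- vapply(1:10, function(s) {
    lab <- sabec_single_run(both, k = 2, table = tab, tau = 2, seed = s)
    mean(lab[1:60] == lab[61:120])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("consensus counting matches brute-force pair counting", {
  withr::with_seed(5, {
    runs <- lapply(1:7, function(i) sample.int(3, 20, replace = TRUE))
  })
  cm <- consensus_matrix(runs)
  expect_equal(cm$n_runs, 7)
  expect_true(isSymmetric(unname(cm$co_count)))
  expect_true(all(diag(cm$co_count) == 7))
  for (i in c(1, 5)) for (j in c(2, 17)) {
    expect_equal(cm$co_count[i, j],
                 sum(vapply(runs, function(l) l[i] == l[j], logical(1))))
  }
  ident <- consensus_matrix(replicate(50, rep(1:2, each = 5), simplify = FALSE))
  expect_true(all(ident$co_count %in% c(0, 50)))
})

test_that("PAC counts strictly ambiguous pairs", {
  stable <- consensus_matrix(replicate(10, rep(1:2, each = 5),
                                       simplify = FALSE))
  expect_equal(pac_score(stable), 0)
  # two orthogonal 2-cluster runs over 4 cells: 4 of the 6 pairs agree in
  # exactly one run (frequency 0.5), the 2 never-together pairs are stable
  half <- consensus_matrix(list(rep(1:2, each = 2), rep(1:2, times = 2)))
  expect_equal(pac_score(half), 4 / 6)
  allhalf <- structure(list(co_count = matrix(5, 4, 4), n_runs = 10),
                       class = "bk_consensus")
  diag(allhalf$co_count) <- 10
  expect_equal(pac_score(allhalf), 1)
})

test_that("variation of information has its closed-form values", {
  a <- rep(1:2, each = 50)
  expect_equal(variation_of_information(a, a), 0)
  expect_equal(variation_of_information(a, rep(1, 100)), log(2),
               tolerance = 1e-12)
  withr::with_seed(6, {
    b <- sample.int(4, 100, replace = TRUE)
    c2 <- sample.int(3, 100, replace = TRUE)
  })
  expect_equal(variation_of_information(b, c2),
               variation_of_information(c2, b))
  expect_gte(variation_of_information(b, c2), 0)
})

test_that("corrected Rand matches an independent implementation and is centred", {
  skip_if_not_installed("mclust")
  withr::with_seed(7, {
    for (i in 1:5) {
      a <- sample.int(4, 200, replace = TRUE)
      b <- sample.int(3, 200, replace = TRUE)
      expect_equal(corrected_rand(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
  a <- rep(1:3, times = 40)
  expect_equal(corrected_rand(a, a), 1)
  withr::with_seed(8, {
    null_vals <- vapply(1:100, function(i) {
      corrected_rand(sample.int(5, 1000, replace = TRUE),
                     sample.int(5, 1000, replace = TRUE))
    }, numeric(1))
  })
  expect_lt(abs(mean(null_vals)), 0.02)
})

test_that("PAM on a block-diagonal consensus recovers the blocks", {
  runs <- replicate(20, rep(1:2, each = 6), simplify = FALSE)
  cm <- consensus_matrix(runs)
  part <- consensus_partition(cm, 2)
  expect_equal(corrected_rand(part, rep(1:2, each = 6)), 1)
  expect_equal(unname(consensus_partition(cm, 12)), 1:12)
})

test_that("outlier pruning finds planted misfits", {
  # cells 1..18 always co-cluster with their label; cells 19,20 never do
  labels <- rep(1:2, each = 10)
  good <- rep(1:2, each = 10)
  runs <- replicate(30, {
    l <- good
    l[19:20] <- 3L  # always off on their own
    l
  }, simplify = FALSE)
  cm <- consensus_matrix(runs)
  pr <- prune_outliers(cm, labels)
  expect_equal(which(!pr$keep), c(19L, 20L))
  # nothing pruned when everyone matches
  cm2 <- consensus_matrix(replicate(10, good, simplify = FALSE))
  pr2 <- prune_outliers(cm2, labels)
  expect_true(all(pr2$keep))
  expect_true(is.na(attr(pr2, "threshold")))
  # singleton label class warns and scores zero
  expect_warning(pr3 <- prune_outliers(cm2, c(rep(1, 19), 9)), "size 1")
  expect_equal(pr3$match_fraction[20], 0)
})

test_that("consensus over restarts separates mixed populations", {
  tab <- small_table()
  d <- two_pop_data(seed = 21)
  sb <- sabec(d, k = 2, table = tab, runs = 12, tau = 10, seed = 40)
  truth <- rep(1:2, each = 60)
  expect_gte(corrected_rand(tidy(sb)$cluster, truth), 0.9)
  gl <- glance(sb)
  expect_lt(gl$pac, 0.3)
  expect_equal(gl$runs, 12)
  expect_s3_class(autoplot(sb), "ggplot")
})

test_that("higher temperature converges in fewer iterations", {
  tab <- small_table()
  d <- two_pop_data(seed = 30)
  iters <- vapply(c(2, 10), function(tau) {
    mean(vapply(1:8, function(s) {
      attr(sabec_single_run(d, k = 2, table = tab, tau = tau, seed = s),
           "iterations")
    }, integer(1)))
  }, numeric(1))
  expect_lte(iters[2], iters[1])
})
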