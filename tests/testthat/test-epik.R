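test_that("BIC scores follow the published penalty and pick 'none' for identical data", {
  tab <- small_table()
  x <- sample_stationary_counts(1, 2, 50, 124, seed = 3)
  b <- bic_select(x, x, tab)
  expect_s3_class(b, "bk_bic")
  expect_equal(b$scenario, "none")
  expect_equal(b$changed, character(0))
  # the penalty of the printed formula: N (log(2n) - log(2 pi)) - 2 L
  expect_equal(b$table$bic,
               b$table$n_free * (log(248) - log(2 * pi)) -
                 2 * b$table$log_likelihood, tolerance = 1e-12)
  # worked arithmetic: 2 free parameters, 124 cells per population, L = -800
  expect_equal(2 * (log(248) - log(2 * pi)) - 2 * (-800), 1607.351,
               tolerance = 1e-3)
  # the all-free likelihood dominates, the shared fit never beats it
  expect_true(all(b$table$log_likelihood[b$table$scenario == "all"] >=
                    b$table$log_likelihood - 1e-9))
})

test_that("BIC scenario likelihoods are ordered by nesting", {
  tab <- small_table()
  dc <- generate_design_c(per_scenario = 2, seed = 5,
                          scenarios = c("none", "k_t"))
  for (i in seq_len(nrow(dc))) {
    b <- bic_select(dc$counts_a[[i]], dc$counts_b[[i]], tab,
                    min_expressing = 0L)
    if (!b$testable) next
    tbl <- b$table
    l <- stats::setNames(tbl$log_likelihood, tbl$scenario)
    expect_lte(l[["none"]], l[["k_on"]] + 1e-9)
    expect_lte(l[["k_on"]], l[["k_on+k_off"]] + 1e-9)
    expect_lte(l[["k_on+k_off"]], l[["all"]] + 1e-9)
  }
})

test_that("BIC detects a planted k_on change under 90% loss", {
  tab <- epik_table()
  hits <- vapply(1:8, function(s) {
    a <- apply_capture(sample_stationary_counts(0.5, 2, 80, 124, seed = 100 + s),
                       0.1, seed = 200 + s)
    b <- apply_capture(sample_stationary_counts(3.0, 2, 80, 124, seed = 300 + s),
                       0.1, seed = 400 + s)
    if (sum(a > 0) < 10 || sum(b > 0) < 10) return(NA)
    "k_on" %in% bic_select(a, b, tab)$changed
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})

test_that("log-sum-exp shifting survives extreme magnitudes", {
  lse <- burstkit:::logsumexp
  expect_equal(lse(c(-1000, -1000)), -1000 + log(2), tolerance = 1e-12)
  expect_equal(lse(c(0, -2000)), 0, tolerance = 1e-12)
  expect_identical(lse(c(-Inf, -Inf)), -Inf)
})

test_that("marginal probability is non-positive and near zero for shared data", {
  tab <- small_table()
  x <- sample_stationary_counts(1, 2, 50, 600, seed = 8)
  for (p in c("k_on", "k_off", "k_t")) {
    mp <- marginal_probability(x, x, tab, p)
    expect_lte(mp, 1e-9)
    expect_gt(mp, -0.5)
  }
  # concentrated, far-apart posteriors push the overlap to the floor
  a <- sample_stationary_counts(0.4, 1, 200, 300, seed = 9)
  b <- sample_stationary_counts(4.8, 1, 20, 300, seed = 10)
  expect_lt(marginal_probability(a, b, tab, "k_on"), -20)
  withr::with_seed(12, {
    for (i in 1:4) {
      xa <- sample_stationary_counts(runif(1, 0.3, 4), runif(1, 0.5, 4),
                                     runif(1, 15, 180), 124)
      xb <- sample_stationary_counts(runif(1, 0.3, 4), runif(1, 0.5, 4),
                                     runif(1, 15, 180), 124)
      if (sum(xa > 0) < 10 || sum(xb > 0) < 10) next
      expect_lte(marginal_probability(xa, xb, tab, "k_t"), 1e-9)
    }
  })
})

test_that("the KS statistic hits its CDF extremes", {
  ks <- burstkit:::ks_stat
  expect_equal(ks(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks(c(1, 2), c(5, 6)), 1)
  expect_equal(ks(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
})

test_that("subsampling KS separates a strong k_t change and stays low under the null", {
  tab <- small_table()
  a <- sample_stationary_counts(1, 1, 40, 124, seed = 14)
  b <- sample_stationary_counts(1, 1, 160, 124, seed = 15)
  ks <- subsample_ks(a, b, tab, seed = 16)
  expect_gte(ks[["k_t"]], 0.9)
  nulls <- vapply(1:5, function(s) {
    x <- sample_stationary_counts(1.5, 2, 60, 124, seed = 20 + s)
    y <- sample_stationary_counts(1.5, 2, 60, 124, seed = 40 + s)
    subsample_ks(x, y, tab, seed = 60 + s)[["k_t"]]
  }, numeric(1))
  expect_lt(mean(nulls < 0.5), 1.01)   # sanity: defined in [0, 1]
  expect_gte(mean(nulls < 0.86), 0.8)  # mostly below the low-regime threshold
  expect_error(subsample_ks(a[1:20], b, tab), "increase frac")
  expect_identical(subsample_ks(a, b, tab, seed = 5),
                   subsample_ks(a, b, tab, seed = 5))
})

test_that("the expressing-cell rule masks weak genes per population", {
  d <- dplyr::bind_rows(
    tibble::tibble(cell = paste0("a", 1:30), population = "A", gene = "g1",
                   count = c(rep(2L, 9), rep(0L, 21))),
    tibble::tibble(cell = paste0("b", 1:30), population = "B", gene = "g1",
                   count = rep(3L, 30)),
    tibble::tibble(cell = paste0("a", 1:30), population = "A", gene = "g2",
                   count = rep(1L, 30)),
    tibble::tibble(cell = paste0("b", 1:30), population = "B", gene = "g2",
                   count = rep(2L, 30)),
    tibble::tibble(cell = paste0("a", 1:30), population = "A", gene = "g3",
                   count = rep(0L, 30)),
    tibble::tibble(cell = paste0("b", 1:30), population = "B", gene = "g3",
                   count = rep(0L, 30)))
  f <- expressed_cell_filter(d)
  testable <- dplyr::summarise(dplyr::group_by(f, gene),
                               ok = all(pass), .groups = "drop")
  expect_equal(testable$ok[testable$gene == "g1"], FALSE)  # 9 expressing in A
  expect_equal(testable$ok[testable$gene == "g2"], TRUE)
  expect_equal(testable$ok[testable$gene == "g3"], FALSE)
})

test_that("method combination follows the published thresholds and set algebra", {
  mp <- c(k_on = -7.0, k_off = -2, k_t = -7.5)
  ks <- c(k_on = 0.80, k_off = 0.2, k_t = 0.80)
  out <- epik_combine(c("k_on"), mp, ks, koff_estimate = 2)
  expect_equal(out$regime, "low")
  expect_equal(out$mp_call, "k_on,k_t")    # -7.0 < -6.3 and -7.5 < -6.8
  expect_equal(out$ks_call, "k_on")        # 0.80 > 0.77 but 0.80 < 0.86
  expect_equal(out$intersection_call, "k_on")
  expect_equal(out$union_call, "k_on,k_t")
  # high regime: k_off is never callable
  out_hi <- epik_combine(c("k_off"), c(k_on = -1, k_off = -50, k_t = -1),
                         c(k_on = 0.1, k_off = 0.99, k_t = 0.1),
                         koff_estimate = 8)
  expect_equal(out_hi$regime, "high")
  expect_equal(out_hi$mp_call, "")
  expect_equal(out_hi$ks_call, "")
  expect_equal(out_hi$intersection_call, "")
})

test_that("epik_compare returns an untestable row for silent genes", {
  tab <- small_table()
  out <- epik_compare(rep(0L, 124), rep(5L, 124), tab)
  expect_false(out$testable)
  expect_true(is.na(out$bic_call))
})

test_that("epik maps over genes and population pairs deterministically", {
  tab <- small_table()
  d <- dplyr::bind_rows(
    population_tibble(1, 2, 60, 60, pop = "A", genes = 2, seed = 70),
    population_tibble(1, 2, 60, 60, pop = "B", genes = 2, seed = 71))
  out <- epik(d, tab, seed = 3, reps = 30)
  expect_equal(nrow(out), 2)         # 1 pair x 2 genes
  expect_setequal(out$gene, c("g1", "g2"))
  out2 <- epik(d, tab, seed = 3, reps = 30)
  expect_identical(out, out2)
})
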