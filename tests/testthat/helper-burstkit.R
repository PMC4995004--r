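# Shared fixtures: small lookup tables are expensive enough to build once and
# cache for the whole run.
.tables <- new.env(parent = emptyenv())

cached_table <- function(name, grid) {
  if (is.null(.tables[[name]])) .tables[[name]] <- build_lookup_table(grid)
  .tables[[name]]
}

# coarse estimation grid (k_off capped at 5): recovery / SABEC unit tests
small_table <- function() {
  cached_table("small", grid_spec(seq(0.2, 5, by = 0.2), seq(0.4, 5, by = 0.4),
                                  seq(10, 200, by = 10), x_max = 250))
}

# very coarse grid for clustering runs
cluster_table <- function() {
  cached_table("cluster", grid_spec(seq(0.5, 5, by = 0.5), seq(1, 10, by = 1),
                                    seq(20, 200, by = 20), x_max = 200))
}

# paper-density axes over the EPiK-relevant ranges
epik_table <- function() {
  cached_table("epik", grid_spec(seq(0.1, 5, by = 0.1), seq(0.4, 10, by = 0.4),
                                 seq(5, 200, by = 5), x_max = 200))
}

# independent oracle for the stationary PMF: the telegraph stationary law is a
# Poisson mixture over a Beta(k_on, k_off) promoter-activity weight
beta_poisson_log_pmf <- function(x, k_on, k_off, k_t) {
  log(stats::integrate(function(p) stats::dpois(x, k_t * p) *
                         stats::dbeta(p, k_on, k_off),
                       0, 1, rel.tol = 1e-12, abs.tol = 0)$value)
}

# long count tibble for one homogeneous population
population_tibble <- function(k_on, k_off, k_t, n, pop = "A", genes = 3,
                              seed = NULL) {
  local({
    if (!is.null(seed)) withr::local_seed(seed)
    purrr::map_dfr(seq_len(genes), function(g) {
      tibble::tibble(cell = paste0(pop, "_", seq_len(n)), population = pop,
                     gene = paste0("g", g),
                     count = sample_stationary_counts(k_on, k_off, k_t, n))
    })
  })
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
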