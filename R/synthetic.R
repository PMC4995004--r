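#' Sample cells from the stationary two-state distribution
#'
#' Inverse-CDF draws from the analytic stationary PMF, with the support
#' ceiling chosen adaptively so the truncated tail mass is below 1e-9. The
#' Gillespie simulator ([gillespie_two_state()]) provides an independent
#' kinetic route to the same distribution and is used to cross-validate this
#' sampler in the test-suite.
#'
#' @inheritParams telegraph_log_pmf
#' @param n Number of cells.
#' @param seed Optional integer seed; the draw is a pure function of
#'   (parameters, n, seed).
#' @return Integer vector of `n` mRNA counts.
#' @export
sample_stationary_counts <- function(k_on, k_off, k_t, n, seed = NULL) {
  stopifnot(n >= 1)
  local_seed_if(seed)
  x_hi <- max(20, ceiling(k_t + 12 * sqrt(k_t + 1) + 20))
  repeat {
    if (x_hi > 1e6) stop("required support ceiling beyond budget")
    pmf <- telegraph_pmf(k_on, k_off, k_t, x_hi)
    if (sum(pmf) >= 1 - 1e-9) break
    x_hi <- x_hi * 2
  }
  sample.int(x_hi + 1L, size = n, replace = TRUE, prob = pmf) - 1L
}

#' Gillespie simulation of the two-state gene
#'
#' Exact stochastic simulation of the reactions off->on (`k_on`), on->off
#' (`k_off`), on->on+mRNA (`k_t`) and per-molecule mRNA decay at rate 1;
#' time is measured in mRNA lifetimes and each trajectory starts at
#' (0 mRNA, promoter off). For `t_end >= 20` the end state is effectively
#' stationary.
#'
#' @inheritParams sample_stationary_counts
#' @param t_end Simulated time span in mRNA lifetimes.
#' @return Tibble with `count` and `state` (`"on"`/`"off"`) per trajectory;
#'   attribute `fraction_on` holds the pooled fraction of time spent on.
#' @export
gillespie_two_state <- function(k_on, k_off, k_t, t_end = 30, n = 1,
                                seed = NULL) {
  local_seed_if(seed)
  m <- cpp_gillespie(k_on, k_off, k_t, t_end, as.integer(n))
  out <- tibble::tibble(count = m[, 1],
                        state = ifelse(m[, 2] == 1L, "on", "off"))
  attr(out, "fraction_on") <- attr(m, "fraction_on")
  out
}

#' Binomial transcript loss (capture thinning)
#'
#' Models the loss of starting material during library preparation: each
#' transcript of each cell survives independently with probability `p` (the
#' benchmarks use `p = 0.1`, i.e. 90% loss). Thinning a beta-Poisson
#' population is equivalent to scaling `k_t` by `p`, which is why estimates
#' downstream live on the captured-count scale.
#'
#' @param counts Integer vector of true per-cell counts.
#' @param p Capture probability in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer vector of captured counts.
#' @export
apply_capture <- function(counts, p, seed = NULL) {
  stopifnot(p > 0, p <= 1)
  if (p == 1) return(as.integer(counts))
  local_seed_if(seed)
  stats::rbinom(length(counts), as.integer(counts), p)
}

#' Estimation benchmark: random parameter sets with 90% transcript loss
#'
#' Design A: `n_sets` parameter triples drawn uniformly with `k_on` in
#' (0, 5), `k_off` in (0, 20) and `k_t` in (0, 600); for each triple a
#' population of cells is sampled from the stationary law and binomially
#' thinned. The per-population cell number is not dictated by the benchmark
#' definition; the default 124 matches the experimental population size.
#'
#' @param n_sets Number of parameter triples.
#' @param n_cells Cells per population.
#' @param capture Capture probability (default 0.1).
#' @param seed Integer seed.
#' @return Tibble with `set`, true `k_on`, `k_off`, `k_t`, and a `counts`
#'   list-column of captured counts.
#' @export
generate_design_a <- function(n_sets = 3000, n_cells = 124, capture = 0.1,
                              seed = NULL) {
  local_seed_if(seed)
  params <- tibble::tibble(set = seq_len(n_sets),
                           k_on = stats::runif(n_sets, 0, 5),
                           k_off = stats::runif(n_sets, 0, 20),
                           k_t = stats::runif(n_sets, 0, 600))
  params$counts <- purrr::pmap(params[c("k_on", "k_off", "k_t")],
    function(k_on, k_off, k_t) {
      apply_capture(sample_stationary_counts(k_on, k_off, k_t, n_cells),
                    capture)
    })
  params
}

#' Built-in base kinetic parameter sets for the clustering benchmark
#'
#' A synthetic stand-in for experimentally fitted parameter values (which are
#' not redistributable): 20 triples spanning the estimable ranges, biased
#' towards the low-expression corner typical of developmental transcription
#' factors.
#'
#' @return Tibble with columns `k_on`, `k_off`, `k_t`.
#' @export
base_kinetic_params <- function() {
  tibble::tibble(
    k_on = c(0.2, 0.3, 0.5, 0.5, 0.8, 1.0, 1.0, 1.2, 1.5, 1.5,
             2.0, 2.0, 2.5, 3.0, 3.0, 3.5, 4.0, 4.0, 4.5, 0.7),
    k_off = c(0.8, 4.0, 1.0, 8.0, 2.0, 0.6, 5.0, 10.0, 1.5, 6.0,
              0.8, 12.0, 3.0, 1.0, 8.0, 2.0, 0.6, 15.0, 4.0, 2.5),
    k_t = c(30, 120, 60, 180, 20, 90, 150, 60, 40, 110,
            25, 170, 80, 35, 130, 55, 95, 190, 70, 15))
}

#' Clustering benchmark: multi-population datasets with known labels
#'
#' Design B: each dataset holds `n_populations` populations of
#' `cells_per_pop` cells measured over `n_genes` genes. Per-population,
#' per-gene parameter triples are drawn from a jittered pool built around a
#' base list (Gaussian jitter with sigma 0.25, 1 and 10 for `k_on`, `k_off`
#' and `k_t` — 5% of the default table ranges), then counts are sampled from
#' the stationary law. Truth labels are retained.
#'
#' @param n_datasets Number of independent datasets.
#' @param n_populations,cells_per_pop,n_genes Dataset shape (defaults
#'   5 x 124 x 18).
#' @param base_params Base triples; defaults to [base_kinetic_params()].
#' @param jitter Named sigmas for the Gaussian jitter.
#' @param pool_size Size of the jittered parameter pool.
#' @param capture Capture probability (default 1: parameters are already on
#'   the captured scale, as when derived from experimental fits).
#' @param seed Integer seed.
#' @return List of datasets; each is a list with `counts` (long tibble
#'   `cell`, `population`, `gene`, `count`) and `params` (tibble
#'   `population`, `gene`, `k_on`, `k_off`, `k_t`).
#' @export
generate_design_b <- function(n_datasets = 100, n_populations = 5,
                              cells_per_pop = 124, n_genes = 18,
                              base_params = base_kinetic_params(),
                              jitter = c(k_on = 0.25, k_off = 1, k_t = 10),
                              pool_size = 100, capture = 1, seed = NULL) {
  local_seed_if(seed)
  base <- base_params[sample.int(nrow(base_params), pool_size, replace = TRUE), ]
  pool <- tibble::tibble(
    k_on = clamp(base$k_on + stats::rnorm(pool_size, 0, jitter[["k_on"]]),
                 0.1, 5),
    k_off = clamp(base$k_off + stats::rnorm(pool_size, 0, jitter[["k_off"]]),
                  0.4, 20),
    k_t = clamp(base$k_t + stats::rnorm(pool_size, 0, jitter[["k_t"]]),
                5, 200))
  genes <- sprintf("g%02d", seq_len(n_genes))
  pops <- sprintf("pop%d", seq_len(n_populations))
  lapply(seq_len(n_datasets), function(d) {
    params <- tidyr::expand_grid(population = pops, gene = genes)
    params <- dplyr::bind_cols(params,
                               pool[sample.int(pool_size, nrow(params),
                                               replace = TRUE), ])
    counts <- dplyr::group_by(params, .data$population, .data$gene) |>
      dplyr::group_modify(function(p, key) {
        x <- sample_stationary_counts(p$k_on, p$k_off, p$k_t, cells_per_pop)
        tibble::tibble(cell_idx = seq_len(cells_per_pop),
                       count = apply_capture(x, capture))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(cell = paste0(.data$population, "_c", .data$cell_idx)) |>
      dplyr::select("cell", "population", "gene", "count")
    list(counts = counts, params = params)
  })
}

epik_scenarios <- function() {
  list(none = character(0),
       k_on = "k_on", k_off = "k_off", k_t = "k_t",
       `k_on+k_off` = c("k_on", "k_off"),
       `k_on+k_t` = c("k_on", "k_t"),
       `k_off+k_t` = c("k_off", "k_t"),
       all = c("k_on", "k_off", "k_t"))
}

#' Paired-population benchmark over the eight change scenarios
#'
#' Design C: pairs of single-gene populations in which a known subset of
#' {`k_on`, `k_off`, `k_t`} differs. Half the pairs have `k_off` in (0, 5)
#' (low regime), half in (5, 10) (high regime); `k_on` is drawn in (0, 5)
#' and `k_t` in (0, 600); both populations are thinned to 10% capture.
#' Unchanged parameters are shared exactly; a changed parameter is redrawn
#' until it differs by at least one default-grid step (0.1 / 0.4 / 5), since
#' an arbitrarily small "change" is unfalsifiable.
#'
#' @param per_scenario Datasets per scenario (split evenly across regimes).
#' @param n_cells Cells per population.
#' @param capture Capture probability.
#' @param seed Integer seed.
#' @param scenarios Subset of scenario names to generate (default all 8).
#' @return Tibble, one row per dataset: `scenario`, `regime`, the two true
#'   triples, and `counts_a` / `counts_b` list-columns.
#' @export
generate_design_c <- function(per_scenario = 200, n_cells = 124,
                              capture = 0.1, seed = NULL,
                              scenarios = names(epik_scenarios())) {
  local_seed_if(seed)
  sc_list <- epik_scenarios()[scenarios]
  min_change <- c(k_on = 0.1, k_off = 0.4, k_t = 5)
  ranges <- list(k_on = c(0, 5), k_t = c(0, 600))
  per_regime <- ceiling(per_scenario / 2)
  rows <- purrr::imap(sc_list, function(changed, sc_name) {
    purrr::map(c("low", "high"), function(regime) {
      koff_range <- if (regime == "low") c(0, 5) else c(5, 10)
      purrr::map(seq_len(per_regime), function(i) {
        a <- c(k_on = stats::runif(1, 0, 5),
               k_off = stats::runif(1, koff_range[1], koff_range[2]),
               k_t = stats::runif(1, 0, 600))
        b <- a
        for (p in changed) {
          rng <- if (p == "k_off") koff_range else ranges[[p]]
          repeat {
            v <- stats::runif(1, rng[1], rng[2])
            if (abs(v - a[[p]]) >= min_change[[p]]) break
          }
          b[[p]] <- v
        }
        draw <- function(pp) {
          apply_capture(
            sample_stationary_counts(pp[["k_on"]], pp[["k_off"]],
                                     pp[["k_t"]], n_cells), capture)
        }
        tibble::tibble(scenario = sc_name, regime = regime,
                       k_on_a = a[["k_on"]], k_off_a = a[["k_off"]],
                       k_t_a = a[["k_t"]],
                       k_on_b = b[["k_on"]], k_off_b = b[["k_off"]],
                       k_t_b = b[["k_t"]],
                       counts_a = list(draw(a)), counts_b = list(draw(b)))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}
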