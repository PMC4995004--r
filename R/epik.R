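#' Published decision thresholds for the EPiK methods
#'
#' Calibrated so the marginal-probability (MP) and subsampling-KS methods
#' each run at roughly a 2% false-positive rate on the paired-population
#' benchmark. Two regimes are distinguished by the inactivation rate:
#' below `k_off = 5` all three parameters are callable; above it `k_off`
#' changes are not detectable (the distribution depends on `k_t / k_off`
#' only), so no `k_off` threshold exists there.
#'
#' @return List with elements `mp` (log-scale, more negative = changed),
#'   `ks` (KS statistic, larger = changed), each split into `low` / `high`
#'   regime vectors, and `koff_regime_cut`.
#' @export
epik_thresholds <- function() {
  list(mp = list(low = c(k_on = -6.3, k_off = -8.5, k_t = -6.8),
                 high = c(k_on = -4.9, k_t = -6.0)),
       ks = list(low = c(k_on = 0.77, k_off = 0.91, k_t = 0.86),
                 high = c(k_on = 0.681, k_t = 0.870)),
       koff_regime_cut = 5)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# reshape a surface vector (k_on-major row order) into [k_t, k_off, k_on]
surface_array <- function(surface, grid) {
  array(surface, dim = c(length(grid$k_t_values), length(grid$k_off_values),
                         length(grid$k_on_values)))
}

param_axis <- c(k_t = 1L, k_off = 2L, k_on = 3L)

# maximum joint log-likelihood with `changed` parameters free per population
# and the others shared on the grid
scenario_logL <- function(arr_a, arr_b, changed) {
  free <- unname(param_axis[changed])
  shared <- setdiff(1:3, free)
  if (length(shared) == 0) return(max(arr_a) + max(arr_b))
  if (length(free) == 0) return(max(arr_a + arr_b))
  ra <- apply(arr_a, shared, max)
  rb <- apply(arr_b, shared, max)
  max(ra + rb)
}

bic_from_surfaces <- function(sa, sb, grid, n_a, n_b, standard_bic = FALSE) {
  arr_a <- surface_array(sa, grid)
  arr_b <- surface_array(sb, grid)
  scen <- epik_scenarios()
  logL <- vapply(scen, function(ch) scenario_logL(arr_a, arr_b, ch),
                 numeric(1))
  n_free <- lengths(scen)
  penalty <- if (standard_bic) n_free * log(n_a + n_b)
             else n_free * (log(n_a + n_b) - log(2 * pi))
  tbl <- tibble::tibble(scenario = names(scen), n_free = n_free,
                        log_likelihood = logL, bic = penalty - 2 * logL)
  ord <- order(tbl$bic, tbl$n_free, tbl$scenario)
  structure(list(scenario = tbl$scenario[ord[1]],
                 changed = scen[[tbl$scenario[ord[1]]]],
                 table = tbl, testable = TRUE),
            class = "bk_bic")
}

#' BIC selection of the changed-parameter scenario
#'
#' For each of the eight scenarios (no parameter changed, each single
#' parameter, each pair, all three) the maximum joint log-likelihood over
#' the lookup grid is computed with the unchanged parameters constrained to
#' be shared between the two populations, then penalised as
#' `BIC_i = N_i (log(2n) - log(2 pi)) - 2 L_i` with `N_i` the number of
#' parameters presumed changed and `2n` the combined cell count. The
#' minimum-BIC scenario wins; ties go to fewer free parameters, then the
#' lexicographically first name.
#'
#' @param counts_a,counts_b Integer count vectors for the two populations.
#' @param table Lookup table.
#' @param min_expressing Both populations must have at least this many
#'   expressing cells (default 10) or the result is flagged untestable.
#' @param standard_bic Use the textbook `N log(2n)` penalty instead of the
#'   published one (sensitivity analysis only).
#' @param log_floor Per-count floor.
#' @return A `bk_bic` list: winning `scenario` name, `changed` parameter
#'   set, the full per-scenario `table`, and `testable`.
#' @export
bic_select <- function(counts_a, counts_b, table, min_expressing = 10L,
                       standard_bic = FALSE, log_floor = -745) {
  if (sum(counts_a > 0) < min_expressing || sum(counts_b > 0) < min_expressing)
    return(structure(list(scenario = NA_character_, changed = NULL,
                          table = NULL, testable = FALSE),
                     class = "bk_bic"))
  sa <- log_likelihood_surface(counts_histogram(counts_a, table$grid$x_max),
                               table, log_floor)
  sb <- log_likelihood_surface(counts_histogram(counts_b, table$grid$x_max),
                               table, log_floor)
  bic_from_surfaces(sa, sb, table$grid, length(counts_a), length(counts_b),
                    standard_bic)
}

mp_from_surfaces <- function(sa, sb, grid, param) {
  axis <- param_axis[[param]]
  marg <- function(s) {
    arr <- surface_array(s, grid)
    tot <- logsumexp(arr)
    apply(arr, axis, logsumexp) - tot
  }
  logsumexp(marg(sa) + marg(sb))
}

#' Marginal-probability score for one kinetic parameter
#'
#' Log-scale overlap of the two populations' marginal posteriors over the
#' tested parameter: for each grid value of the parameter the likelihood is
#' marginalised (log-sum-exp) over the joint values of the other two, each
#' population's marginal is normalised, and the score is the log of the
#' inner product of the two marginals. Near 0 means the populations agree
#' on the parameter; strongly negative means it changed. All sums use the
#' max-shift log-sum-exp, so the score is immune to underflow.
#'
#' @inheritParams bic_select
#' @param param One of `"k_on"`, `"k_off"`, `"k_t"`.
#' @return Scalar `<= 0` (up to rounding); `NA` if untestable.
#' @export
marginal_probability <- function(counts_a, counts_b, table, param,
                                 min_expressing = 10L, log_floor = -745) {
  param <- match.arg(param, c("k_on", "k_off", "k_t"))
  if (sum(counts_a > 0) < min_expressing || sum(counts_b > 0) < min_expressing)
    return(NA_real_)
  sa <- log_likelihood_surface(counts_histogram(counts_a, table$grid$x_max),
                               table, log_floor)
  sb <- log_likelihood_surface(counts_histogram(counts_b, table$grid$x_max),
                               table, log_floor)
  mp_from_surfaces(sa, sb, table$grid, param)
}

ks_stat <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

#' Subsampling Kolmogorov-Smirnov distance per kinetic parameter
#'
#' Repeatedly subsamples a fraction of the cells of each population without
#' replacement, fits the kinetic parameters to every subsample, and returns
#' for each parameter the maximum absolute distance between the two
#' populations' empirical CDFs of estimates. Only the raw KS statistic is
#' returned: the resampling reuses cells, so KS p-values would be biased
#' and are deliberately not computed.
#'
#' @inheritParams bic_select
#' @param frac Subsample fraction (default 0.25).
#' @param reps Number of subsamples per population (default 100).
#' @param seed Optional integer seed.
#' @param min_cells Minimum subsample size (default 10).
#' @return Named numeric vector `k_on`, `k_off`, `k_t` of KS statistics in
#'   `[0, 1]`.
#' @export
subsample_ks <- function(counts_a, counts_b, table, frac = 0.25, reps = 100,
                         seed = NULL, min_cells = 10L, log_floor = -745) {
  m_a <- floor(frac * length(counts_a))
  m_b <- floor(frac * length(counts_b))
  if (m_a < min_cells || m_b < min_cells)
    stop("subsample sizes ", m_a, "/", m_b, " below ", min_cells,
         "; increase frac")
  local_seed_if(seed)
  x_max <- table$grid$x_max
  draw_hists <- function(counts, m) {
    counts <- pmin(as.integer(counts), x_max)
    vapply(seq_len(reps), function(r) {
      tabulate(sample(counts, m) + 1L, nbins = x_max + 1L)
    }, numeric(x_max + 1L))
  }
  H <- cbind(draw_hists(counts_a, m_a), draw_hists(counts_b, m_b))
  surf <- log_likelihood_surfaces(H, table, log_floor)
  rows <- cpp_col_argmax(surf)
  est <- table$params[rows, ]
  ia <- seq_len(reps); ib <- reps + seq_len(reps)
  vapply(c(k_on = "k_on", k_off = "k_off", k_t = "k_t"), function(p) {
    ks_stat(est[[p]][ia], est[[p]][ib])
  }, numeric(1))
}

#' Which genes have enough expressing cells to test
#'
#' The published exclusion rule: a gene is testable only if at least
#' `min_cells` cells express it (count > 0) in every population compared.
#'
#' @param data Long count tibble with `population`.
#' @param min_cells Threshold (default 10).
#' @return Tibble `gene`, `population`, `n_expressing`, `pass`.
#' @export
expressed_cell_filter <- function(data, min_cells = 10L) {
  data <- as_count_table(data)
  dplyr::group_by(data, .data$gene, .data$population) |>
    dplyr::summarise(n_expressing = sum(.data$count > 0), .groups = "drop") |>
    dplyr::mutate(pass = .data$n_expressing >= min_cells)
}

#' Combine the three EPiK methods into a per-gene call
#'
#' The `k_off` regime is chosen from the (pooled) `k_off` estimate: below
#' the cut all three parameters are callable, above it `k_off` is never
#' called. MP flags a parameter when its score falls below the regime
#' threshold, KS when its statistic exceeds it. The conservative call is
#' the intersection of the BIC scenario with both flag sets; the union of
#' MP and KS is also reported.
#'
#' @param bic A [bic_select()] result (or a character vector of changed
#'   parameters).
#' @param mp Named numeric vector of MP scores (`k_on`, `k_off`, `k_t`).
#' @param ks Named numeric vector of KS statistics.
#' @param koff_estimate Pooled-data `k_off` estimate used to pick the
#'   regime.
#' @param thresholds An [epik_thresholds()] list.
#' @param direction Optional sign of the expression change (+1 / -1 / 0).
#' @return One-row tibble with the regime, per-method flag sets (as
#'   comma-joined strings; empty string = no change called), the
#'   intersection and union calls, and the direction.
#' @export
epik_combine <- function(bic, mp, ks, koff_estimate,
                         thresholds = epik_thresholds(), direction = NA) {
  bic_set <- if (inherits(bic, "bk_bic")) bic$changed else bic
  regime <- if (koff_estimate < thresholds$koff_regime_cut) "low" else "high"
  mp_thr <- thresholds$mp[[regime]]
  ks_thr <- thresholds$ks[[regime]]
  mp_set <- names(mp_thr)[!is.na(mp[names(mp_thr)]) &
                            mp[names(mp_thr)] < mp_thr]
  ks_set <- names(ks_thr)[!is.na(ks[names(ks_thr)]) &
                            ks[names(ks_thr)] > ks_thr]
  inter <- intersect(intersect(bic_set, mp_set), ks_set)
  uni <- union(mp_set, ks_set)
  join <- function(s) paste(sort(s), collapse = ",")
  tibble::tibble(regime = regime, bic_call = join(bic_set),
                 mp_call = join(mp_set), ks_call = join(ks_set),
                 intersection_call = join(inter), union_call = join(uni),
                 direction = direction)
}

#' Full EPiK comparison of two count vectors (one gene, two populations)
#'
#' Runs the expressing-cell filter, the BIC scenario selection, the three
#' marginal-probability scores and the subsampling-KS statistics, picks the
#' `k_off` regime from the pooled maximum-likelihood fit, and combines the
#' methods. Likelihood surfaces are computed once and shared.
#'
#' @inheritParams subsample_ks
#' @param thresholds An [epik_thresholds()] list.
#' @param min_expressing Expressing-cell rule (default 10).
#' @return One-row tibble: `testable`, regime, per-method outputs
#'   (`bic_call`, `mp_k_on` ... `ks_k_t`), combined calls and direction.
#' @export
epik_compare <- function(counts_a, counts_b, table,
                         thresholds = epik_thresholds(), frac = 0.25,
                         reps = 100, seed = NULL, min_expressing = 10L,
                         log_floor = -745) {
  blank <- tibble::tibble(testable = FALSE, regime = NA_character_,
                          bic_call = NA_character_,
                          mp_k_on = NA_real_, mp_k_off = NA_real_,
                          mp_k_t = NA_real_,
                          ks_k_on = NA_real_, ks_k_off = NA_real_,
                          ks_k_t = NA_real_,
                          koff_estimate = NA_real_,
                          mp_call = NA_character_, ks_call = NA_character_,
                          intersection_call = NA_character_,
                          union_call = NA_character_, direction = NA_real_)
  if (sum(counts_a > 0) < min_expressing ||
      sum(counts_b > 0) < min_expressing) return(blank)
  # the subsampling method needs workable subsample sizes; smaller populations
  # are untestable rather than an error at the pipeline level
  if (floor(frac * length(counts_a)) < 10 || floor(frac * length(counts_b)) < 10)
    return(blank)
  grid <- table$grid
  sa <- log_likelihood_surface(counts_histogram(counts_a, grid$x_max),
                               table, log_floor)
  sb <- log_likelihood_surface(counts_histogram(counts_b, grid$x_max),
                               table, log_floor)
  bic <- bic_from_surfaces(sa, sb, grid, length(counts_a), length(counts_b))
  mp <- vapply(c(k_on = "k_on", k_off = "k_off", k_t = "k_t"),
               function(p) mp_from_surfaces(sa, sb, grid, p), numeric(1))
  ks <- subsample_ks(counts_a, counts_b, table, frac = frac, reps = reps,
                     seed = seed, log_floor = log_floor)
  pooled <- ml_estimate(c(counts_a, counts_b), table, min_expressing = 0L,
                        log_floor = log_floor)
  direction <- sign(mean(counts_b) - mean(counts_a))
  comb <- epik_combine(bic, mp, ks, pooled$k_off, thresholds, direction)
  dplyr::bind_cols(
    tibble::tibble(testable = TRUE, regime = comb$regime,
                   bic_call = comb$bic_call,
                   mp_k_on = mp[["k_on"]], mp_k_off = mp[["k_off"]],
                   mp_k_t = mp[["k_t"]],
                   ks_k_on = ks[["k_on"]], ks_k_off = ks[["k_off"]],
                   ks_k_t = ks[["k_t"]],
                   koff_estimate = pooled$k_off),
    comb[c("mp_call", "ks_call", "intersection_call", "union_call",
           "direction")])
}

#' EPiK across a dataset: every gene, chosen population pairs
#'
#' @param data Long count tibble with `population`.
#' @param table Lookup table.
#' @param pairs Two-column data frame (`pop_a`, `pop_b`); defaults to all
#'   unordered population pairs.
#' @param seed Base seed; each gene-pair combination derives its own.
#' @param ... Passed to [epik_compare()].
#' @return Tibble with one row per gene and population pair.
#' @export
epik <- function(data, table, pairs = NULL, seed = 1, ...) {
  data <- as_count_table(data)
  pops <- unique(data$population)
  if (is.null(pairs)) {
    cmb <- utils::combn(pops, 2)
    pairs <- tibble::tibble(pop_a = cmb[1, ], pop_b = cmb[2, ])
  }
  genes <- unique(data$gene)
  grid_jobs <- tidyr::expand_grid(pairs, gene = genes)
  purrr::pmap(grid_jobs, function(pop_a, pop_b, gene) {
    ca <- data$count[data$population == pop_a & data$gene == gene]
    cb <- data$count[data$population == pop_b & data$gene == gene]
    job_seed <- (seed + 7919 * match(gene, genes) +
                   31 * which(pairs$pop_a == pop_a &
                                pairs$pop_b == pop_b)[1]) %% .Machine$integer.max
    dplyr::bind_cols(tibble::tibble(gene = gene, pop_a = pop_a,
                                    pop_b = pop_b),
                     epik_compare(ca, cb, table, seed = job_seed, ...))
  }) |> dplyr::bind_rows()
}
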