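#' Histogram of mRNA counts over the table support
#'
#' Counts above `x_max` are clipped to `x_max` with a warning; the lookup
#' table covers `0:x_max` and the Ct scaling keeps real data in range, so
#' clipping only ever touches simulated tails.
#'
#' @param counts Non-negative integer vector, one entry per cell.
#' @param x_max Count ceiling of the companion lookup table.
#' @return A `bk_histogram`: list with `counts_per_value` (length
#'   `x_max + 1`) and `n_cells`.
#' @export
counts_histogram <- function(counts, x_max) {
  if (length(counts) == 0) stop("counts must contain at least one cell")
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  n_clip <- sum(counts > x_max)
  if (n_clip > 0) {
    warning(n_clip, " count(s) above x_max = ", x_max, " clipped")
    counts[counts > x_max] <- as.integer(x_max)
  }
  structure(list(counts_per_value = tabulate(counts + 1L, nbins = x_max + 1L),
                 n_cells = length(counts), x_max = as.integer(x_max)),
            class = "bk_histogram")
}

#' Log-likelihood of every table row for a population of cells
#'
#' The population log-likelihood L(params | X) = sum_i ln P(x_i | params) is
#' a dot product of the count histogram with each table row, so the whole
#' surface is one matrix-vector product. Rows whose probability underflowed
#' are floored at `log_floor` so a single impossible count cannot erase the
#' entire surface.
#'
#' @param hist A [counts_histogram()] result.
#' @param table A [build_lookup_table()] result with matching `x_max`.
#' @param log_floor Floor applied to per-count log-probabilities (default
#'   -745, just inside double range).
#' @return Numeric vector over table rows.
#' @export
log_likelihood_surface <- function(hist, table, log_floor = -745) {
  stopifnot(inherits(hist, "bk_histogram"), inherits(table, "bk_lookup"))
  if (hist$x_max != table$grid$x_max)
    stop("histogram x_max (", hist$x_max, ") does not match table (",
         table$grid$x_max, ")")
  # 0 * -Inf would poison the product, hence the floor
  as.vector(floored_log_pmf(table, log_floor) %*% hist$counts_per_value)
}

# surfaces for many histograms at once: columns of H are histograms
log_likelihood_surfaces <- function(H, table, log_floor = -745) {
  floored_log_pmf(table, log_floor) %*% H
}

#' Maximum-likelihood kinetic parameters for one cell population
#'
#' Finds the table row maximising the population log-likelihood. Ties are
#' broken deterministically by the lowest row index (k_on-major order), so
#' for all-zero data the fit lands on the smallest available `k_t`.
#' Estimates are on the captured-count scale: no capture-efficiency
#' correction is applied, matching the interpretation that absolute
#' parameter values are not comparable across protocols.
#'
#' @param counts Integer vector of per-cell counts.
#' @param table Lookup table.
#' @param min_expressing Refuse populations with fewer than this many cells
#'   expressing (count > 0); default 10, the published exclusion rule. Set 0
#'   for internal use on arbitrarily small clusters.
#' @param log_floor See [log_likelihood_surface()].
#' @return A `bk_fit`: list with `k_on`, `k_off`, `k_t`, `log_likelihood`,
#'   `row`, `n_cells`, `n_expressing`.
#' @examples
#' tab <- build_lookup_table(grid_spec(c(1, 2), c(1, 2), c(10, 20), x_max = 60))
#' fit <- ml_estimate(rpois(50, 8), tab)
#' tidy(fit)
#' @export
ml_estimate <- function(counts, table, min_expressing = 10L, log_floor = -745) {
  n_expr <- sum(counts > 0)
  if (n_expr < min_expressing)
    stop("only ", n_expr, " expressing cells; fewer than the required ",
         min_expressing)
  hist <- counts_histogram(counts, table$grid$x_max)
  surface <- log_likelihood_surface(hist, table, log_floor)
  row <- which.max(surface)  # first maximum = lowest row index on ties
  p <- table$params[row, ]
  structure(list(k_on = p$k_on, k_off = p$k_off, k_t = p$k_t,
                 log_likelihood = surface[row], row = row,
                 n_cells = hist$n_cells, n_expressing = n_expr),
            class = "bk_fit")
}

#' @export
print.bk_fit <- function(x, ...) {
  cat(sprintf("<bk_fit> k_on = %g, k_off = %g, k_t = %g (logL = %.3f, n = %d)\n",
              x$k_on, x$k_off, x$k_t, x$log_likelihood, x$n_cells))
  invisible(x)
}

#' @rdname ml_estimate
#' @param x A `bk_fit`.
#' @param ... Unused.
#' @method tidy bk_fit
#' @export
tidy.bk_fit <- function(x, ...) {
  tibble::tibble(parameter = c("k_on", "k_off", "k_t"),
                 estimate = c(x$k_on, x$k_off, x$k_t))
}

#' @rdname ml_estimate
#' @method glance bk_fit
#' @export
glance.bk_fit <- function(x, ...) {
  tibble::tibble(k_on = x$k_on, k_off = x$k_off, k_t = x$k_t,
                 log_likelihood = x$log_likelihood, row = x$row,
                 n_cells = x$n_cells, n_expressing = x$n_expressing)
}

#' Fit kinetic parameters per gene and population across a tidy count table
#'
#' Tidy front end to [ml_estimate()]: the input holds one row per
#' cell-by-gene measurement, and a fit is returned for every
#' (population, gene) combination with enough expressing cells; the others
#' are reported with `testable = FALSE` rather than dropped.
#'
#' @param data Data frame with columns `cell`, `gene`, `count` and optionally
#'   `population` (a single population is assumed when absent).
#' @param table Lookup table.
#' @param min_expressing Exclusion rule, see [ml_estimate()].
#' @return Tibble with one row per population-gene pair: estimates, log
#'   likelihood, cell counts and a `testable` flag.
#' @export
estimate_kinetics <- function(data, table, min_expressing = 10L) {
  data <- as_count_table(data)
  dplyr::group_by(data, .data$population, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      n_expr <- sum(d$count > 0)
      if (n_expr < min_expressing)
        return(tibble::tibble(k_on = NA_real_, k_off = NA_real_,
                              k_t = NA_real_, log_likelihood = NA_real_,
                              n_cells = nrow(d), n_expressing = n_expr,
                              testable = FALSE))
      fit <- ml_estimate(d$count, table, min_expressing = 0L)
      dplyr::mutate(glance(fit)[c("k_on", "k_off", "k_t", "log_likelihood",
                                  "n_cells")],
                    n_expressing = n_expr, testable = TRUE)
    }) |>
    dplyr::ungroup()
}

# canonical long count table: cell, population, gene, count
as_count_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("cell", "gene", "count")
  if (!all(need %in% names(data)))
    stop("count data needs columns cell, gene, count")
  if (!"population" %in% names(data)) data$population <- "all"
  if (any(!is.finite(data$count)) || any(data$count < 0))
    stop("counts must be finite and non-negative")
  data
}
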