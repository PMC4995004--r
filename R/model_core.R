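#' Log-probability of an mRNA count under the two-state promoter model
#'
#' Evaluates the stationary distribution of the telegraph model of bursting
#' transcription: a promoter switches on at rate `k_on`, off at rate `k_off`,
#' and transcribes at rate `k_t` while on, with all three rates normalised to
#' the mRNA degradation rate (so they are dimensionless, per mRNA lifetime).
#' The stationary law is the beta-Poisson distribution whose PMF involves the
#' confluent hypergeometric function 1F1; it is evaluated in log space with a
#' positive-term Kummer series, so no cancellation occurs even at large `k_t`.
#'
#' @param x Non-negative integer count (vectorised).
#' @param k_on,k_off,k_t Kinetic rates, finite and `>= 0`, normalised to the
#'   degradation rate.
#' @return `ln P(x | k_on, k_off, k_t)` for each `x`; `-Inf` only where the
#'   probability is exactly zero (e.g. `k_t = 0`, `x > 0`) or underflows.
#' @examples
#' telegraph_log_pmf(0, 1, 1, 0)        # no transcription: P(0) = 1
#' telegraph_log_pmf(3, 2, 0, 4)        # k_off = 0 collapses to Poisson(4)
#' @export
telegraph_log_pmf <- function(x, k_on, k_off, k_t) {
  stopifnot(length(k_on) == 1, length(k_off) == 1, length(k_t) == 1)
  x <- as.integer(x)
  if (any(x < 0)) stop("x must be non-negative")
  v <- cpp_telegraph_log_pmf(k_on, k_off, k_t, max(x))
  v[x + 1L]
}

#' Stationary PMF vector of the two-state model
#'
#' @inheritParams telegraph_log_pmf
#' @param x_max Largest count evaluated; the vector covers `0:x_max`.
#' @return Numeric probability vector of length `x_max + 1`.
#' @examples
#' p <- telegraph_pmf(0.5, 0.5, 100, x_max = 200)  # bimodal regime
#' @export
telegraph_pmf <- function(k_on, k_off, k_t, x_max) {
  stopifnot(x_max >= 1)
  exp(cpp_telegraph_log_pmf(k_on, k_off, k_t, as.integer(x_max)))
}

#' Large-k_off limiting distribution (negative binomial)
#'
#' At large `k_off` the stationary law converges to a negative binomial that
#' depends on the burst-size ratio `k_t / k_off` only, which is why `k_off`
#' and `k_t` become unidentifiable individually in that regime: doubling both
#' leaves this limit unchanged.
#'
#' @inheritParams telegraph_log_pmf
#' @return `ln P'(x)` under the limiting negative binomial with size `k_on`
#'   and success probability `k_off / (k_off + k_t)`.
#' @export
high_koff_log_pmf <- function(x, k_on, k_off, k_t) {
  if (k_off <= 0) stop("k_off must be > 0 for the large-k_off limit")
  x <- as.integer(x)
  if (any(x < 0)) stop("x must be non-negative")
  if (k_t == 0) return(ifelse(x == 0L, 0, -Inf))
  stats::dnbinom(x, size = k_on, prob = k_off / (k_off + k_t), log = TRUE)
}

#' Parameter grid specification for the lookup table
#'
#' The default grid mirrors the published table: `k_on` from 0.1 to 5 every
#' 0.1, `k_off` from 0.4 to 20 every 0.4, `k_t` from 5 to 200 every 5
#' (100,000 triples), with counts supported on `0:200`.
#'
#' @param k_on_values,k_off_values,k_t_values Strictly increasing non-negative
#'   grid axes.
#' @param x_max Count ceiling (counts above it are clipped downstream).
#' @return A `bk_grid` object.
#' @export
grid_spec <- function(k_on_values = seq(0.1, 5, by = 0.1),
                      k_off_values = seq(0.4, 20, by = 0.4),
                      k_t_values = seq(5, 200, by = 5),
                      x_max = 200L) {
  check_axis <- function(v, nm) {
    if (length(v) < 1 || any(!is.finite(v)) || any(v < 0) ||
        is.unsorted(v, strictly = TRUE))
      stop(nm, " must be strictly increasing and non-negative")
  }
  check_axis(k_on_values, "k_on_values")
  check_axis(k_off_values, "k_off_values")
  check_axis(k_t_values, "k_t_values")
  stopifnot(x_max >= 1)
  structure(
    list(k_on_values = as.numeric(k_on_values),
         k_off_values = as.numeric(k_off_values),
         k_t_values = as.numeric(k_t_values),
         x_max = as.integer(x_max)),
    class = "bk_grid")
}

#' @export
print.bk_grid <- function(x, ...) {
  cat("<bk_grid> ", length(x$k_on_values), " x ", length(x$k_off_values),
      " x ", length(x$k_t_values), " = ",
      length(x$k_on_values) * length(x$k_off_values) * length(x$k_t_values),
      " parameter sets, x_max = ", x$x_max, "\n", sep = "")
  invisible(x)
}

grid_n_rows <- function(grid) {
  length(grid$k_on_values) * length(grid$k_off_values) * length(grid$k_t_values)
}

#' Precompute the log-PMF lookup table over a parameter grid
#'
#' One row per parameter triple in the Cartesian product of the grid axes, in
#' `k_on`-major order (`k_on` slowest, then `k_off`, then `k_t`); columns are
#' counts `0:x_max`. The table turns likelihood evaluation for a whole
#' population into a single matrix product with the count histogram.
#'
#' @param grid A [grid_spec()] object.
#' @param max_cells Refusal threshold on `rows * (x_max + 1)` table entries
#'   (default 5e7, roughly 400 MB of doubles).
#' @param log_floor Per-count log-probabilities below this are floored at
#'   construction (default -745, just inside double range), so a single
#'   impossible count can never erase a whole population's likelihood
#'   surface.
#' @return A `bk_lookup` object with elements `grid`, `log_pmf` (matrix) and
#'   `params` (tibble `row`, `k_on`, `k_off`, `k_t`).
#' @examples
#' tab <- build_lookup_table(grid_spec(1, 2, 50, x_max = 100))
#' @export
build_lookup_table <- function(grid, max_cells = 5e7, log_floor = -745) {
  stopifnot(inherits(grid, "bk_grid"))
  n_entries <- grid_n_rows(grid) * (grid$x_max + 1)
  if (n_entries > max_cells)
    stop("lookup table would hold ", format(n_entries, big.mark = ","),
         " entries, above the budget of ", format(max_cells, big.mark = ","),
         "; thin the grid or raise max_cells")
  log_pmf <- cpp_build_table(grid$k_on_values, grid$k_off_values,
                             grid$k_t_values, grid$x_max)
  log_pmf[log_pmf < log_floor] <- log_floor
  params <- tidyr::expand_grid(k_on = grid$k_on_values,
                               k_off = grid$k_off_values,
                               k_t = grid$k_t_values)
  params <- tibble::add_column(params, row = seq_len(nrow(params)),
                               .before = 1)
  structure(list(grid = grid, log_pmf = log_pmf, params = params,
                 floor = log_floor),
            class = "bk_lookup")
}

# matrix with the requested floor; no copy when the built-in floor suffices
floored_log_pmf <- function(table, log_floor) {
  if (!is.null(table$floor) && log_floor <= table$floor) table$log_pmf
  else pmax(table$log_pmf, log_floor)
}

#' @export
print.bk_lookup <- function(x, ...) {
  cat("<bk_lookup> ", nrow(x$log_pmf), " parameter sets, counts 0:",
      x$grid$x_max, "\n", sep = "")
  invisible(x)
}

#' @rdname build_lookup_table
#' @param x A `bk_lookup` object.
#' @param ... Unused.
#' @method tidy bk_lookup
#' @export
tidy.bk_lookup <- function(x, ...) x$params

#' Persist / restore a lookup table as gzip CSV
#'
#' Values are written with 17 significant digits so the round trip is
#' bit-exact. Columns: `k_on`, `k_off`, `k_t`, then `x0..x<x_max>`.
#'
#' @param table A `bk_lookup` object.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `write_lookup_table()` returns `path` invisibly;
#'   `read_lookup_table()` returns the restored `bk_lookup`.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "bk_lookup"))
  df <- cbind(table$params[c("k_on", "k_off", "k_t")],
              as.data.frame(table$log_pmf))
  names(df)[-(1:3)] <- paste0("x", 0:table$grid$x_max)
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path, log_floor = -745) {
  df <- utils::read.csv(path, check.names = FALSE)
  axes <- lapply(df[c("k_on", "k_off", "k_t")], function(v) sort(unique(v)))
  x_max <- ncol(df) - 4L
  grid <- grid_spec(axes$k_on, axes$k_off, axes$k_t, x_max = x_max)
  tab <- build_lookup_skeleton(grid)
  stored <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(stored) <- NULL
  # rows must come back in k_on-major order
  ord <- order(match(df$k_on, axes$k_on), match(df$k_off, axes$k_off),
               match(df$k_t, axes$k_t))
  stored <- stored[ord, , drop = FALSE]
  stored[stored < log_floor] <- log_floor
  tab$log_pmf <- stored
  tab$floor <- log_floor
  tab
}

build_lookup_skeleton <- function(grid) {
  params <- tidyr::expand_grid(k_on = grid$k_on_values,
                               k_off = grid$k_off_values,
                               k_t = grid$k_t_values)
  params <- tibble::add_column(params, row = seq_len(nrow(params)),
                               .before = 1)
  structure(list(grid = grid, log_pmf = NULL, params = params),
            class = "bk_lookup")
}

lookup_row_index <- function(table, k_on, k_off, k_t) {
  g <- table$grid
  i <- match(k_on, g$k_on_values)
  j <- match(k_off, g$k_off_values)
  k <- match(k_t, g$k_t_values)
  if (anyNA(c(i, j, k))) stop("parameters do not lie on the table grid")
  ((i - 1L) * length(g$k_off_values) + (j - 1L)) * length(g$k_t_values) + k
}

# Nearest grid row to an arbitrary triple (used when cluster parameters come
# from the same table they index into, so normally an exact match).
lookup_nearest_row <- function(table, k_on, k_off, k_t) {
  g <- table$grid
  i <- which.min(abs(g$k_on_values - k_on))
  j <- which.min(abs(g$k_off_values - k_off))
  k <- which.min(abs(g$k_t_values - k_t))
  ((i - 1L) * length(g$k_off_values) + (j - 1L)) * length(g$k_t_values) + k
}
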