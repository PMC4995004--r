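#' Log-likelihood of one cell under a cluster's kinetic parameters
#'
#' Sums, over genes, the log-probability of the cell's count under the
#' cluster's per-gene parameter triple, read from the lookup table (cluster
#' parameters always lie on the grid; off-grid triples snap to the nearest
#' row).
#'
#' @param cell_counts Named integer vector: one count per gene.
#' @param cluster_params Data frame with columns `gene`, `k_on`, `k_off`,
#'   `k_t`, covering every gene of `cell_counts`.
#' @param table Lookup table.
#' @param log_floor Per-count floor, see [log_likelihood_surface()].
#' @return Scalar log-likelihood.
#' @export
cluster_log_likelihood <- function(cell_counts, cluster_params, table,
                                   log_floor = -745) {
  genes <- names(cell_counts)
  if (is.null(genes) || !all(genes %in% cluster_params$gene))
    stop("cluster_params must cover every gene of cell_counts")
  cp <- cluster_params[match(genes, cluster_params$gene), ]
  rows <- mapply(lookup_nearest_row, cp$k_on, cp$k_off, cp$k_t,
                 MoreArgs = list(table = table))
  x <- pmin(as.integer(cell_counts), table$grid$x_max)
  sum(pmax(table$log_pmf[cbind(rows, x + 1L)], log_floor))
}

#' Annealed cluster-assignment probabilities
#'
#' Converts per-cluster log-likelihoods into assignment probabilities with an
#' annealing schedule: `p_i` is proportional to
#' `exp(tau^t * (L_i - max_j L_j))`. At iteration `t = 0` this is the
#' ordinary likelihood-ratio (softmax) assignment; as `t` grows the inverse
#' temperature `tau^t` sharpens the distribution towards the best-fitting
#' cluster, so early iterations reassign cells freely and later ones
#' essentially harden.
#'
#' @param cell_logL Numeric vector of per-cluster log-likelihoods.
#' @param tau Annealing temperature, `> 1` (default 10).
#' @param t Iteration counter, `>= 0`.
#' @return Probability vector over clusters.
#' @examples
#' assignment_probabilities(c(-10, -11), tau = 10, t = 0)  # ~ (0.731, 0.269)
#' @export
assignment_probabilities <- function(cell_logL, tau, t) {
  stopifnot(tau > 1, t >= 0, length(cell_logL) >= 1)
  if (all(!is.finite(cell_logL))) {
    warning("all cluster log-likelihoods are -Inf; uniform assignment")
    return(rep(1 / length(cell_logL), length(cell_logL)))
  }
  z <- tau^t * (cell_logL - max(cell_logL))
  p <- exp(z)
  p / sum(p)
}

# long tibble -> cells x genes integer matrix (rownames = cell ids)
counts_matrix <- function(data) {
  data <- as_count_table(data)
  wide <- tidyr::pivot_wider(data, id_cols = "cell", names_from = "gene",
                             values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cell
  if (anyNA(m)) stop("count matrix has missing cell/gene combinations")
  storage.mode(m) <- "integer"
  m
}

#' One annealed clustering run
#'
#' Starts from uniform-random labels and alternates (i) per-cluster,
#' per-gene maximum-likelihood parameter estimation over the lookup grid
#' (the exact argmax [ml_estimate()] computes, batched as one matrix
#' product) and (ii) probabilistic reassignment of every cell via
#' [assignment_probabilities()]. Terminates when fewer than
#' `swap_tol` of the cells change label in an iteration, or after
#' `max_iter` iterations. A cluster that empties is re-seeded with the
#' single worst-fitting cell.
#'
#' @param data Long count tibble (`cell`, `gene`, `count`) or cells x genes
#'   integer matrix.
#' @param k Number of clusters.
#' @param table Lookup table.
#' @param tau Annealing temperature (default 10).
#' @param max_iter Iteration cap (default 100).
#' @param swap_tol Convergence threshold on the fraction of cells swapping
#'   clusters (default 0.05).
#' @param seed Optional integer seed.
#' @param log_floor Per-count floor.
#' @return Integer label vector (1..k) named by cell, with attributes
#'   `iterations`, `converged` and `repairs`.
#' @export
sabec_single_run <- function(data, k, table, tau = 10, max_iter = 100,
                             swap_tol = 0.05, seed = NULL, log_floor = -745) {
  X <- if (is.matrix(data)) data else counts_matrix(data)
  n <- nrow(X); G <- ncol(X)
  stopifnot(k >= 1, n >= k)
  local_seed_if(seed)
  x_max <- table$grid$x_max
  idx <- pmin(X, x_max) + 1L                      # count -> table column
  lp <- floored_log_pmf(table, log_floor)
  labels <- sample.int(k, n, replace = TRUE)
  iterations <- 0L; converged <- FALSE; repairs <- 0L
  L <- NULL
  for (t in seq_len(max_iter) - 1L) {
    # repair empty clusters with the currently worst-fitting cell
    empty <- setdiff(seq_len(k), unique(labels))
    for (e in empty) {
      victim <- if (is.null(L)) sample.int(n, 1)
                else which.min(apply(L, 1, max))
      labels[victim] <- e
      repairs <- repairs + 1L
    }
    # (i) ML parameters per (cluster, gene): histograms -> one GEMM -> argmax
    H <- matrix(0, x_max + 1L, k * G)
    for (g in seq_len(G)) for (cl in seq_len(k)) {
      H[, (g - 1L) * k + cl] <- tabulate(idx[labels == cl, g],
                                         nbins = x_max + 1L)
    }
    surf <- lp %*% H
    best_rows <- cpp_col_argmax(surf)
    # (ii) per-cell log-likelihood under each cluster, annealed resampling
    L <- matrix(0, n, k)
    for (g in seq_len(G)) {
      rows_g <- best_rows[(g - 1L) * k + seq_len(k)]
      L <- L + t(lp[rows_g, , drop = FALSE][, idx[, g], drop = FALSE])
    }
    beta <- tau^t
    Z <- beta * (L - L[cbind(seq_len(n), max.col(L, ties.method = "first"))])
    gumbel <- -log(-log(matrix(stats::runif(n * k), n, k)))
    new_labels <- max.col(Z + gumbel, ties.method = "first")
    swapped <- mean(new_labels != labels)
    labels <- new_labels
    iterations <- t + 1L
    if (swapped < swap_tol) { converged <- TRUE; break }
  }
  names(labels) <- rownames(X)
  structure(labels, iterations = iterations, converged = converged,
            repairs = repairs)
}

#' Consensus clustering of cells by bursting kinetics (SABEC)
#'
#' Runs [sabec_single_run()] `runs` times from independent random
#' initialisations (seeds `seed + 1 .. seed + runs`) and aggregates the
#' partitions into a consensus matrix counting how often each pair of cells
#' lands in the same cluster.
#'
#' @inheritParams sabec_single_run
#' @param runs Number of restarts (default 50).
#' @param seed Base seed; run `r` uses `seed + r`.
#' @return A `bk_sabec` object: `labels` (cells x runs matrix), `consensus`
#'   (a `bk_consensus`), `k`, and per-run convergence diagnostics.
#' @export
sabec <- function(data, k, table, runs = 50, tau = 10, max_iter = 100,
                  swap_tol = 0.05, seed = 1, log_floor = -745) {
  X <- if (is.matrix(data)) data else counts_matrix(data)
  run_list <- lapply(seq_len(runs), function(r) {
    sabec_single_run(X, k, table, tau = tau, max_iter = max_iter,
                     swap_tol = swap_tol, seed = seed + r,
                     log_floor = log_floor)
  })
  labels <- do.call(cbind, run_list)
  diag_tbl <- tibble::tibble(
    run = seq_len(runs),
    iterations = vapply(run_list, attr, integer(1), "iterations"),
    converged = vapply(run_list, attr, logical(1), "converged"))
  structure(list(labels = labels, consensus = consensus_matrix(run_list),
                 k = k, runs = diag_tbl, cells = rownames(X)),
            class = "bk_sabec")
}

#' @export
print.bk_sabec <- function(x, ...) {
  cat("<bk_sabec> ", length(x$cells), " cells, k = ", x$k, ", ",
      nrow(x$runs), " runs (", sum(x$runs$converged), " converged)\n",
      sep = "")
  invisible(x)
}

#' @rdname sabec
#' @param x A `bk_sabec`.
#' @param ... Unused.
#' @method tidy bk_sabec
#' @export
tidy.bk_sabec <- function(x, ...) {
  tibble::tibble(cell = x$cells,
                 cluster = consensus_partition(x$consensus, x$k))
}

#' @rdname sabec
#' @method glance bk_sabec
#' @export
glance.bk_sabec <- function(x, ...) {
  tibble::tibble(k = x$k, runs = nrow(x$runs),
                 pac = pac_score(x$consensus),
                 mean_iterations = mean(x$runs$iterations),
                 prop_converged = mean(x$runs$converged))
}

#' Co-clustering consensus matrix
#'
#' @param runs List of label vectors (or a cells x runs matrix), all over the
#'   same cells.
#' @return A `bk_consensus`: `co_count` (symmetric cells x cells integer
#'   matrix, diagonal = `n_runs`) and `n_runs`.
#' @export
consensus_matrix <- function(runs) {
  if (is.matrix(runs)) runs <- lapply(seq_len(ncol(runs)), function(j) runs[, j])
  n <- length(runs[[1]])
  if (any(lengths(runs) != n)) stop("all runs must cover the same cells")
  co <- matrix(0L, n, n)
  for (l in runs) co <- co + outer(l, l, "==")
  dimnames(co) <- list(names(runs[[1]]), names(runs[[1]]))
  structure(list(co_count = co, n_runs = length(runs)),
            class = "bk_consensus")
}

#' @export
print.bk_consensus <- function(x, ...) {
  cat("<bk_consensus> ", nrow(x$co_count), " cells over ", x$n_runs,
      " runs\n", sep = "")
  invisible(x)
}

#' Proportion of ambiguously clustered pairs (PAC)
#'
#' Fraction of unordered off-diagonal cell pairs whose co-clustering
#' frequency lies strictly between `lower` and `upper`; lower PAC means a
#' more stable consensus.
#'
#' @param cm A [consensus_matrix()] result.
#' @param lower,upper Ambiguity band (defaults 0.10 and 0.90).
#' @return Scalar in `[0, 1]`.
#' @export
pac_score <- function(cm, lower = 0.10, upper = 0.90) {
  stopifnot(inherits(cm, "bk_consensus"), cm$n_runs >= 1)
  f <- cm$co_count[upper.tri(cm$co_count)] / cm$n_runs
  mean(f > lower & f < upper)
}

#' Variation of information between two partitions
#'
#' `VI = H(a) + H(b) - 2 I(a; b)` with natural-log entropies; 0 iff the
#' partitions are identical (up to relabelling), symmetric in its arguments.
#'
#' @param a,b Label vectors over the same cells.
#' @return Non-negative scalar.
#' @export
variation_of_information <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same cells")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- sum(joint[joint > 0] *
              log(joint[joint > 0] / outer(pa, pb)[joint > 0]))
  max(0, H(pa) + H(pb) - 2 * mi)
}

#' Corrected (adjusted) Rand index
#'
#' Hubert-Arabie chance-corrected pair-counting agreement: 1 iff identical
#' partitions, expectation ~0 for independent random labelings.
#'
#' @inheritParams variation_of_information
#' @return Scalar `<= 1`.
#' @export
corrected_rand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same cells")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Cut a consensus matrix into k clusters (PAM)
#'
#' Partitioning around medoids on the co-clustering dissimilarity
#' `1 - co_count / n_runs`; the PAM build phase is deterministic, so the cut
#' is reproducible.
#'
#' @param cm A [consensus_matrix()] result.
#' @param k Number of clusters.
#' @return Integer label vector.
#' @export
consensus_partition <- function(cm, k) {
  stopifnot(inherits(cm, "bk_consensus"))
  n <- nrow(cm$co_count)
  if (k >= n) return(stats::setNames(seq_len(n), rownames(cm$co_count)))
  d <- stats::as.dist(1 - cm$co_count / cm$n_runs)
  cluster::pam(d, k, diss = TRUE, cluster.only = TRUE)
}

#' Flag cells that do not co-cluster with their own labelled population
#'
#' For each cell the match fraction is the mean co-clustering frequency with
#' the other cells carrying the same reference label. Sorting these
#' ascending, the automatic threshold sits at the largest single-step
#' increase within the lower half of the curve (the steepest part of its
#' rise); cells below it are masked. The threshold can be overridden.
#'
#' @param cm A [consensus_matrix()] result.
#' @param labels Reference labels (e.g. FACS populations) for every cell.
#' @param threshold Optional manual match-fraction cutoff; cells strictly
#'   below it are pruned.
#' @return Tibble `cell`, `label`, `match_fraction`, `keep`; attribute
#'   `threshold` holds the cutoff used (NA when nothing is pruned).
#' @export
prune_outliers <- function(cm, labels, threshold = NULL) {
  stopifnot(inherits(cm, "bk_consensus"))
  n <- nrow(cm$co_count)
  if (length(labels) != n) stop("labels must be given for all cells")
  f <- cm$co_count / cm$n_runs
  match_fraction <- vapply(seq_len(n), function(i) {
    same <- which(labels == labels[i])
    same <- setdiff(same, i)
    if (length(same) == 0) {
      warning("label class of size 1 at cell ", i, "; match fraction 0")
      return(0)
    }
    mean(f[i, same])
  }, numeric(1))
  if (is.null(threshold)) {
    s <- sort(match_fraction)
    half <- max(1L, floor(n / 2))
    steps <- diff(s)[seq_len(min(half, n - 1L))]
    threshold <- if (length(steps) == 0 || max(steps) <= 0) NA_real_
                 else s[which.max(steps) + 1L]
  }
  keep <- if (is.na(threshold)) rep(TRUE, n) else match_fraction >= threshold
  out <- tibble::tibble(
    cell = if (is.null(rownames(cm$co_count))) as.character(seq_len(n))
           else rownames(cm$co_count),
    label = labels, match_fraction = match_fraction, keep = keep)
  attr(out, "threshold") <- threshold
  out
}
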