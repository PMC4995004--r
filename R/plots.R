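#' Plot a consensus matrix as a co-clustering heatmap
#'
#' Cells are ordered by a PAM cut of the consensus (or by `order_by` labels
#' when given) so stable blocks appear along the diagonal.
#'
#' @param object A `bk_consensus`.
#' @param k Number of clusters used for the ordering cut (default 2).
#' @param order_by Optional label vector used to order cells instead.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bk_consensus
#' @export
autoplot.bk_consensus <- function(object, k = 2, order_by = NULL, ...) {
  n <- nrow(object$co_count)
  ord <- if (is.null(order_by)) order(consensus_partition(object, k))
         else order(order_by)
  f <- object$co_count[ord, ord] / object$n_runs
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$frequency <- as.vector(f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$frequency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering\nfrequency") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bk_consensus
#' @method autoplot bk_sabec
#' @export
autoplot.bk_sabec <- function(object, ...) {
  autoplot.bk_consensus(object$consensus, k = object$k, ...)
}

#' Plot observed counts against the fitted stationary distribution
#'
#' @param object A `bk_fit` from [ml_estimate()].
#' @param counts The counts the fit was computed from.
#' @param x_max Plot range ceiling (default: just past the largest count).
#' @param ... Unused.
#' @return A ggplot object overlaying the count histogram (as a density)
#'   with the fitted two-state PMF.
#' @method autoplot bk_fit
#' @export
autoplot.bk_fit <- function(object, counts, x_max = NULL, ...) {
  x_max <- x_max %||% (max(counts) + 5)
  obs <- tibble::tibble(count = counts)
  fit <- tibble::tibble(count = 0:x_max,
                        p = telegraph_pmf(object$k_on, object$k_off,
                                          object$k_t, x_max))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 1, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = fit, ggplot2::aes(y = .data$p),
                       colour = "firebrick") +
    ggplot2::labs(x = "mRNA count", y = "probability",
                  subtitle = sprintf("k_on = %g, k_off = %g, k_t = %g",
                                     object$k_on, object$k_off, object$k_t)) +
    ggplot2::theme_minimal()
}

#' Match-fraction curve used for outlier pruning
#'
#' @param pruning A [prune_outliers()] result.
#' @return A ggplot of the sorted match-fraction curve with the threshold
#'   marked.
#' @export
plot_match_fraction <- function(pruning) {
  df <- dplyr::arrange(pruning, .data$match_fraction)
  df$rank <- seq_len(nrow(df))
  thr <- attr(pruning, "threshold")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data$match_fraction,
                                        colour = .data$keep)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "cells (sorted)", y = "% match with own label") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) p <- p + ggplot2::geom_hline(yintercept = thr,
                                                linetype = "dashed")
  p
}
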