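#' Scale normalised qPCR Ct values to bounded mRNA-count surrogates
#'
#' Each unit decrease in Ct corresponds to a doubling of transcript
#' abundance. Per gene the conversion is
#' `count = floor(x_max * 2^(min(Ct) - Ct))`, with the minimum taken over
#' *all* cells of *all* populations jointly, so the per-gene scale factor is
#' shared across populations — a prerequisite for comparing kinetic
#' parameters between them. The most-expressed cell of every gene therefore
#' maps to exactly `x_max`. Housekeeping normalisation is assumed done
#' upstream; no absolute copy-number calibration is attempted (the platform
#' constants cancel by construction).
#'
#' @param data Data frame with columns `cell`, `gene`, `ct` and optionally
#'   `population`. Lower Ct means higher expression.
#' @param x_max Count ceiling matching the lookup table (default 200).
#' @param sentinel Optional Ct value coding "no visible expression" (e.g. 15
#'   on some platforms, 40 or the limit of detection on others); such wells
#'   map to count 0 and are excluded from the per-gene minimum.
#' @return Tibble with columns `cell`, `population`, `gene`, `count`.
#' @examples
#' ct <- tibble::tibble(cell = c("c1", "c2", "c3"), gene = "Gata1",
#'                      ct = c(12, 13, 15))
#' ct_to_counts(ct, x_max = 200)           # 200, 100, 25
#' ct_to_counts(ct, x_max = 200, sentinel = 15)  # 200, 100, 0
#' @export
ct_to_counts <- function(data, x_max = 200L, sentinel = NULL) {
  data <- tibble::as_tibble(data)
  need <- c("cell", "gene", "ct")
  if (!all(need %in% names(data)))
    stop("Ct data needs columns cell, gene, ct")
  if (!"population" %in% names(data)) data$population <- "all"
  is_sent <- if (is.null(sentinel)) rep(FALSE, nrow(data))
             else !is.na(data$ct) & data$ct == sentinel
  if (any(!is.finite(data$ct) & !is_sent))
    stop("Ct values must be finite (or equal to the sentinel)")
  out <- dplyr::group_by(data, .data$gene) |>
    dplyr::group_modify(function(d, key) {
      sent <- if (is.null(sentinel)) rep(FALSE, nrow(d)) else d$ct == sentinel
      expressed <- d$ct[!sent]
      if (length(expressed) == 0)
        stop("gene ", key$gene, " has no expressed (non-sentinel) Ct value")
      count <- floor(x_max * 2^(min(expressed) - d$ct))
      count[sent] <- 0
      dplyr::mutate(d, count = as.integer(count))
    }) |>
    dplyr::ungroup()
  dplyr::select(out, "cell", "population", "gene", "count")
}

#' Read / write cells-by-genes matrices as CSV
#'
#' The canonical on-disk dialect: a header row of gene names, first column
#' `cell` of cell identifiers, optional second column `population`. TSV is
#' detected from the file extension.
#'
#' @param path File path (`.csv` or `.tsv`, optionally gzipped).
#' @param value_col Name for the measurement column of the long tibble
#'   returned (`"count"` or `"ct"`).
#' @return A long tibble `cell`, (`population`,) `gene`, value.
#' @export
read_cells_by_genes <- function(path, value_col = "count") {
  delim <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  id_cols <- intersect(c("cell", "population"), names(wide))
  if (!"cell" %in% id_cols) stop("expected a 'cell' identifier column")
  tidyr::pivot_longer(wide, -dplyr::all_of(id_cols),
                      names_to = "gene", values_to = value_col)
}

#' @rdname read_cells_by_genes
#' @param data Long tibble as produced by [read_cells_by_genes()].
#' @export
write_cells_by_genes <- function(data, path, value_col = "count") {
  id_cols <- intersect(c("cell", "population"), names(data))
  wide <- tidyr::pivot_wider(data, id_cols = dplyr::all_of(id_cols),
                             names_from = "gene",
                             values_from = dplyr::all_of(value_col))
  readr::write_csv(wide, path)
  invisible(path)
}
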