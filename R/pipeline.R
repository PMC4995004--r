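#' Run the full single-cell bursting-kinetics pipeline
#'
#' Orchestrates normalisation (Ct to counts, when Ct input is given),
#' per-population kinetic-parameter estimation, SABEC consensus clustering,
#' outlier pruning, and EPiK population-pair comparisons. When pruning is
#' enabled, EPiK runs on both the pruned and the unpruned cells and the
#' per-gene consistency intersection of the two conservative calls is
#' reported, so a call must survive outlier removal to stand. All stage
#' outputs, seeds and settings land in a JSON manifest, and the run is a
#' pure function of (config, seed): identical inputs give identical outputs.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `counts` (long tibble / CSV path) or `ct` (+ optional `sentinel`);
#'   `table` (a `bk_lookup` or CSV path from [write_lookup_table()]);
#'   `x_max` (default: the table's); `seed`; optional `out_dir` to write
#'   CSV results and `manifest.json`; `sabec` sub-list (`k`, `runs`, `tau`,
#'   `enabled`); `prune` (logical, default `TRUE` when SABEC runs); `epik`
#'   sub-list (`pairs`, `frac`, `reps`); `min_expressing`.
#' @return List with `counts`, `fits`, `sabec` (or NULL), `pruning` (or
#'   NULL), `epik` (tibble; columns from the unpruned run plus, when
#'   pruning is on, `intersection_call_pruned` and `consistent_call`), and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  table <- config$table
  if (is.character(table)) table <- read_lookup_table(table)
  stopifnot(inherits(table, "bk_lookup"))
  x_max <- config$x_max %||% table$grid$x_max
  min_expressing <- config$min_expressing %||% 10L

  # -- stage 1: counts (direct, or normalised from Ct)
  counts <- if (!is.null(config$counts)) {
    if (is.character(config$counts)) read_cells_by_genes(config$counts)
    else tibble::as_tibble(config$counts)
  } else if (!is.null(config$ct)) {
    ct <- if (is.character(config$ct))
      read_cells_by_genes(config$ct, value_col = "ct")
    else tibble::as_tibble(config$ct)
    ct_to_counts(ct, x_max = x_max, sentinel = config$sentinel)
  } else stop("config needs either counts or ct input")
  counts <- as_count_table(counts)

  # -- stage 2: per-population ML fits
  fits <- estimate_kinetics(counts, table, min_expressing = min_expressing)

  # -- stage 3: SABEC consensus clustering
  sb_cfg <- config$sabec %||% list()
  sabec_res <- NULL
  if (isTRUE(sb_cfg$enabled %||% TRUE)) {
    k <- sb_cfg$k %||% length(unique(counts$population))
    sabec_res <- sabec(counts, k = k, table = table,
                       runs = sb_cfg$runs %||% 50,
                       tau = sb_cfg$tau %||% 10, seed = seed)
  }

  # -- stage 4: outlier pruning against the reference labels
  pruning <- NULL
  do_prune <- isTRUE(config$prune %||% !is.null(sabec_res))
  if (do_prune && !is.null(sabec_res)) {
    cell_pop <- dplyr::distinct(counts, .data$cell, .data$population)
    labels <- cell_pop$population[match(sabec_res$cells, cell_pop$cell)]
    pruning <- prune_outliers(sabec_res$consensus, labels,
                              threshold = config$prune_threshold)
  }

  # -- stage 5: EPiK on unpruned (and pruned) cells
  ep_cfg <- config$epik %||% list()
  epik_full <- epik(counts, table, pairs = ep_cfg$pairs, seed = seed,
                    frac = ep_cfg$frac %||% 0.25,
                    reps = ep_cfg$reps %||% 100,
                    min_expressing = min_expressing)
  epik_res <- epik_full
  if (!is.null(pruning)) {
    kept <- pruning$cell[pruning$keep]
    epik_pruned <- epik(dplyr::filter(counts, .data$cell %in% kept), table,
                        pairs = ep_cfg$pairs, seed = seed,
                        frac = ep_cfg$frac %||% 0.25,
                        reps = ep_cfg$reps %||% 100,
                        min_expressing = min_expressing)
    key <- c("gene", "pop_a", "pop_b")
    merged <- dplyr::left_join(
      epik_full,
      dplyr::select(epik_pruned, dplyr::all_of(key),
                    intersection_call_pruned = "intersection_call"),
      by = key)
    merged$consistent_call <- purrr::map2_chr(
      merged$intersection_call, merged$intersection_call_pruned,
      function(a, b) {
        if (is.na(a) || is.na(b)) return(NA_character_)
        paste(intersect(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]]),
              collapse = ",")
      })
    epik_res <- merged
  }

  manifest <- list(
    seed = seed, x_max = x_max, min_expressing = min_expressing,
    n_cells = length(unique(counts$cell)),
    n_genes = length(unique(counts$gene)),
    populations = sort(unique(counts$population)),
    table_rows = nrow(table$log_pmf),
    sabec = if (!is.null(sabec_res)) list(k = sabec_res$k,
                                          runs = nrow(sabec_res$runs)),
    pruned = !is.null(pruning),
    prune_threshold = if (!is.null(pruning)) attr(pruning, "threshold"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(config$out_dir, f))
    w(counts, "counts.csv"); w(fits, "fits.csv"); w(epik_res, "epik_calls.csv")
    if (!is.null(pruning)) w(pruning, "pruning.csv")
    if (!is.null(sabec_res))
      w(tidy(sabec_res), "consensus_partition.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(counts = counts, fits = fits, sabec = sabec_res, pruning = pruning,
       epik = epik_res, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
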