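#' Run the full biclustering pipeline
#'
#' Preprocess (clip, filter, window items) -> mine maximal frequent
#' itemsets -> map to biclusters (min_col filter) -> score with empirical
#' p-values and keep p <= alpha -> merge same-condition-set overlapping
#' biclusters -> build gene set networks.  Deterministic given
#' `params$rng_seed`.
#'
#' @param mat expression matrix (genes x conditions) or the result of
#'   [read_expression_matrix()].
#' @param params a [fimbic_params()].
#' @return An object of class `fimbic_result`: list with
#'   * `biclusters`: merged, significant biclusters (tibble),
#'   * `raw_biclusters`: scored candidates before filtering/merging,
#'   * `networks`: a `gene_set_network_list` (possibly empty),
#'   * `params`, `cache` (null ensembles used), and summary `counts`.
#' @examples
#' sim <- simulate_expression(60, 10, list(implant_block(1:12, 1:4)), seed = 1)
#' res <- fimbic(sim$matrix, fimbic_params(min_row = 8, n_perm = 200))
#' res$biclusters
#' @export
fimbic <- function(mat, params = fimbic_params()) {
  mat <- validate_expression_matrix(mat)
  counts <- list()
  db <- generate_items(mat, params)
  counts$n_items <- nrow(db$items)
  itemsets <- mine_maximal(db, params$min_row)
  counts$n_itemsets <- nrow(itemsets)
  cand <- itemsets_to_biclusters(itemsets, db, params)
  counts$n_candidates <- nrow(cand)
  cache <- null_cache(mat, params$rng_seed)
  scored <- score_biclusters(cand, cache, params$n_perm)
  sig <- filter_significant(scored, params$alpha)
  counts$n_significant <- nrow(sig)
  merged <- merge_all(sig, cache, params)
  counts$n_merged <- nrow(merged)
  networks <- if (nrow(merged) > 0) build_network(merged)
              else structure(list(), class = "gene_set_network_list")
  counts$n_networks <- length(networks)
  structure(
    list(biclusters = merged, raw_biclusters = scored, networks = networks,
         params = params, cache = cache, counts = counts,
         db_stats = db$column_stats),
    class = "fimbic_result"
  )
}

#' @export
print.fimbic_result <- function(x, ...) {
  c0 <- x$counts
  cat("<fimbic_result>\n")
  cat(sprintf("  items: %d   maximal itemsets: %d   candidates: %d\n",
              c0$n_items, c0$n_itemsets, c0$n_candidates))
  cat(sprintf("  significant: %d   merged: %d   networks: %d\n",
              c0$n_significant, c0$n_merged, c0$n_networks))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the merged biclusters of a pipeline result
#'
#' @param x a `fimbic_result`.
#' @param ... unused.
#' @return the merged bicluster tibble, one row per bicluster.
#' @method tidy fimbic_result
#' @export
tidy.fimbic_result <- function(x, ...) x$biclusters

#' One-row summary of a pipeline run
#'
#' @param x a `fimbic_result`.
#' @param ... unused.
#' @return a one-row tibble of stage counts and parameters.
#' @method glance fimbic_result
#' @export
glance.fimbic_result <- function(x, ...) {
  tibble::tibble(
    n_items = x$counts$n_items,
    n_itemsets = x$counts$n_itemsets,
    n_candidates = x$counts$n_candidates,
    n_significant = x$counts$n_significant,
    n_merged = x$counts$n_merged,
    n_networks = x$counts$n_networks,
    min_row = x$params$min_row, min_col = x$params$min_col,
    bin = x$params$bin, sd_coeff = x$params$sd_coeff,
    alpha = x$params$alpha, n_perm = x$params$n_perm,
    rng_seed = x$params$rng_seed
  )
}

#' Write the outputs of a pipeline run
#'
#' Writes merged biclusters (TSV + JSON-lines), a JSON parameter sidecar,
#' per-network GraphML and flat tables, and per-node gene lists into
#' `dir`.
#'
#' @param result a `fimbic_result`.
#' @param dir output directory (created if missing).
#' @param order bicluster ordering for the TSV (see [write_biclusters()]).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, order = "by_size") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_biclusters(result$biclusters, file.path(dir, "biclusters.tsv"), order = order)
  write_biclusters_jsonl(result$biclusters, file.path(dir, "biclusters.jsonl"))
  jsonlite::write_json(unclass(result$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(result$networks)) {
    net <- result$networks[[i]]
    write_graphml(net, file.path(dir, sprintf("network%02d.graphml", i)))
    write_network_tables(net, file.path(dir, sprintf("network%02d", i)))
  }
  invisible(dir)
}
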