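#' Enumerate maximal frequent itemsets
#'
#' Exact, exhaustive enumeration of the maximal frequent itemsets of the
#' transaction database: sets of items whose supporting genes (the
#' intersection of the member items' gene sets) number at least `min_row`,
#' such that no strict superset of items is still frequent.  The search is
#' a depth-first set-intersection enumeration with support-ascending child
#' ordering, parent-equivalence pruning and subsumption pruning, run in
#' compiled code.
#'
#' @param db a `transaction_db` from [generate_items()].
#' @param min_row minimum support (gene count), >= 2.
#' @return A tibble with one row per maximal frequent itemset: `item_ids`
#'   (list of integer item ids), `genes` (list of supporting gene ids),
#'   `conditions` (list of distinct condition ids touched), `n_genes`,
#'   `n_conditions`.  Ordered by support size descending, then
#'   deterministically.
#' @examples
#' m <- matrix(rnorm(80), 10, 8,
#'             dimnames = list(paste0("g", 1:10), paste0("c", 1:8)))
#' db <- generate_items(m, fimbic_params(min_row = 3))
#' mine_maximal(db, min_row = 3)
#' @export
mine_maximal <- function(db, min_row) {
  stopifnot(inherits(db, "transaction_db"), min_row >= 2)
  n_genes <- length(db$gene_ids)
  raw <- .mine_maximal_cpp(db$item_genes, n_genes, as.integer(min_row))
  if (length(raw) == 0) {
    return(tibble::tibble(
      item_ids = list(), genes = list(), conditions = list(),
      n_genes = integer(), n_conditions = integer()
    ))
  }
  cond_of <- db$items$condition
  rows <- lapply(raw, function(ids) {
    ids <- sort(ids)
    sup <- Reduce(intersect, db$item_genes[ids])
    tibble::tibble(
      item_ids = list(ids),
      genes = list(sort(db$gene_ids[sup])),
      conditions = list(sort(unique(cond_of[ids]))),
      n_genes = length(sup),
      n_conditions = length(unique(cond_of[ids]))
    )
  })
  out <- dplyr::bind_rows(rows)
  key <- vapply(out$genes, set_key, "")
  out[order(-out$n_genes, -out$n_conditions, key), ]
}

#' Convert maximal itemsets to candidate biclusters
#'
#' Maps each itemset to the pair (support genes, distinct conditions),
#' drops itemsets spanning fewer than `min_col` conditions, collapses
#' duplicate (genes, conditions) pairs, and checks column coherence: in
#' every selected condition the clipped values of the support genes span at
#' most that column's MAX_DIFF.
#'
#' @param itemsets output of [mine_maximal()].
#' @param db the `transaction_db` the itemsets were mined from.
#' @param params a [fimbic_params()] (uses `min_col`).
#' @return A bicluster tibble: `genes`, `conditions` (list-columns),
#'   `n_genes`, `n_conditions`, `size` (= cell count), `t_stat`, `p_value`
#'   (NA until scored); ordered by size descending with the global
#'   tie-break.
#' @export
itemsets_to_biclusters <- function(itemsets, db, params = fimbic_params()) {
  keep <- itemsets$n_conditions >= params$min_col
  its <- itemsets[keep, ]
  if (nrow(its) == 0) return(empty_biclusters())
  b <- new_biclusters(its$genes, its$conditions)
  key <- paste(vapply(b$genes, set_key, ""), vapply(b$conditions, set_key, ""), sep = "|")
  b <- b[!duplicated(key), ]
  assert_column_coherence(b, db)
  b[order_biclusters(b, "size"), ]
}

# Constructor for the bicluster tibble; sorts each gene/condition set.
new_biclusters <- function(genes, conditions, t_stat = NA_real_, p_value = NA_real_) {
  genes <- lapply(genes, function(g) sort(as.character(g)))
  conditions <- lapply(conditions, function(cc) sort(as.character(cc)))
  n_g <- lengths(genes)
  n_c <- lengths(conditions)
  tibble::tibble(
    genes = genes, conditions = conditions,
    n_genes = as.integer(n_g), n_conditions = as.integer(n_c),
    size = as.integer(n_g * n_c),
    t_stat = rep_len(as.double(t_stat), length(genes)),
    p_value = rep_len(as.double(p_value), length(genes))
  )
}

empty_biclusters <- function() {
  tibble::tibble(
    genes = list(), conditions = list(),
    n_genes = integer(), n_conditions = integer(), size = integer(),
    t_stat = double(), p_value = double()
  )
}

# Every bicluster must satisfy max - min <= MAX_DIFF per selected column,
# on clipped values.  Internal sanity check; tolerance covers float noise.
assert_column_coherence <- function(b, db) {
  if (is.null(db$clipped)) return(invisible(b))   # hand-built db: nothing to check
  st <- db$column_stats
  md <- stats::setNames(st$max_diff, st$condition)
  for (i in seq_len(nrow(b))) {
    g <- b$genes[[i]]
    for (cc in b$conditions[[i]]) {
      vals <- db$clipped[g, cc]
      if (diff(range(vals)) > md[[cc]] + 1e-9) {
        stop("internal error: bicluster violates column coherence in ", cc, call. = FALSE)
      }
    }
  }
  invisible(b)
}
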