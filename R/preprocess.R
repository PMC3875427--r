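# Per-column discretization of an expression matrix into overlapping
# "items": sets of genes whose clipped values in one condition fall inside
# a sliding window of width MAX_DIFF = 6 * SD / bin.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Clip a column's outliers into Mean +/- 3 SD
#'
#' Mean and SD are computed on the original values (population SD, divide
#' by n); values outside Mean +/- 3 SD are set to the nearer bound, all
#' other values pass through unchanged.  Clipping fixes the per-column
#' extremes at Mean +/- 3 SD, which is what makes the window width
#' `(MAX - MIN) / bin` collapse to `6 * SD / bin`.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @return A list with `values` (clipped vector), `mean`, `sd`.
#' @examples
#' clip_outliers(c(rnorm(20), 50))
#' @export
clip_outliers <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  m <- mean(x)
  s <- pop_sd(x)
  list(values = pmin(pmax(x, m - 3 * s), m + 3 * s), mean = m, sd = s)
}

#' Per-column coherence width
#'
#' With MAX and MIN fixed at Mean +/- 3 SD by the clipping convention,
#' `(MAX - MIN) / bin` is always `6 * sd / bin`.
#'
#' @param sd column standard deviation (>= 0).
#' @param bin positive integer bin count.
#' @return the window width MAX_DIFF.
#' @examples
#' max_diff(sd = 7, bin = 7)  # 6
#' @export
max_diff <- function(sd, bin) {
  stopifnot(sd >= 0, bin >= 1)
  6 * sd / bin
}

#' Weak-signal filter for one column
#'
#' A gene is retained for a column only if its clipped value lies at least
#' `sd_coeff * sd` away from the column mean; values inside that band are
#' considered undifferentiated and take part in no item of the column.
#'
#' @param values clipped column values (from [clip_outliers()]).
#' @param mean,sd column statistics (from [clip_outliers()]).
#' @param sd_coeff non-negative band half-width in SD units.
#' @return logical mask of retained genes.
#' @export
sd_filter <- function(values, mean, sd, sd_coeff) {
  stopifnot(sd_coeff >= 0)
  abs(values - mean) >= sd_coeff * sd
}

#' Build the transaction database of sliding-window items
#'
#' For every condition: clip outliers, drop weak values, sort the retained
#' genes by value, and slide a window of width `MAX_DIFF = 6 * SD / bin`
#' gene-wise: each retained gene anchors one item containing every retained
#' gene whose value lies in the closed interval
#' `[v_anchor, v_anchor + MAX_DIFF]`.  Before deduplication the item count
#' of a column equals its retained gene count; items with identical gene
#' sets within a column are collapsed (anchor multiplicity recorded).
#' Columns with zero SD are degenerate and contribute no items.
#'
#' @param mat expression matrix (genes x conditions).
#' @param params a [fimbic_params()] object (uses `bin`, `sd_coeff`).
#' @return An object of class `transaction_db`: list with
#'   * `items`: tibble (item_id, condition, genes list-column, value_lo,
#'     value_hi, n_anchors),
#'   * `column_stats`: tibble (condition, mean, sd, max_diff, n_retained),
#'   * `gene_ids`, `condition_ids`: the matrix dimnames,
#'   * `item_genes`: integer-index gene sets per item (internal, 1-based),
#'   * `transactions`: per-gene item-id list.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
#' generate_items(m, fimbic_params(min_row = 3))
#' @export
generate_items <- function(mat, params = fimbic_params()) {
  mat <- validate_expression_matrix(mat)
  genes <- rownames(mat)
  conds <- colnames(mat)

  stats_rows <- vector("list", length(conds))
  item_rows <- list()
  item_genes <- list()
  next_id <- 1L
  clipped <- mat

  for (j in seq_along(conds)) {
    x <- mat[, j]
    cl <- clip_outliers(x)
    clipped[, j] <- cl$values
    md <- max_diff(cl$sd, params$bin)
    retained <- if (cl$sd == 0) integer() else
      which(sd_filter(cl$values, cl$mean, cl$sd, params$sd_coeff))
    stats_rows[[j]] <- tibble::tibble(
      condition = conds[j], mean = cl$mean, sd = cl$sd,
      max_diff = md, n_retained = length(retained)
    )
    if (length(retained) == 0) next
    v <- cl$values[retained]
    ord <- order(v, retained)           # stable: value then gene index
    ridx <- retained[ord]
    rv <- v[ord]
    n <- length(ridx)
    prev_key <- ""
    for (a in seq_len(n)) {
      hi <- rv[a] + md
      first <- a
      while (first > 1L && rv[first - 1L] == rv[a]) first <- first - 1L
      last <- a
      while (last < n && rv[last + 1L] <= hi) last <- last + 1L
      members <- ridx[first:last]
      key <- set_key(members)
      if (key == prev_key) {
        k <- length(item_rows)
        item_rows[[k]]$n_anchors <- item_rows[[k]]$n_anchors + 1L
        next
      }
      prev_key <- key
      item_rows[[length(item_rows) + 1L]] <- list(
        item_id = next_id, condition = conds[j],
        genes = genes[members], value_lo = rv[a], value_hi = rv[last],
        n_anchors = 1L
      )
      item_genes[[next_id]] <- sort(members)
      next_id <- next_id + 1L
    }
  }

  if (length(item_rows) == 0) {
    stop("degenerate input: no column yields any item", call. = FALSE)
  }

  items <- dplyr::bind_rows(lapply(item_rows, function(r) {
    tibble::tibble(
      item_id = r$item_id, condition = r$condition,
      genes = list(sort(r$genes)), value_lo = r$value_lo,
      value_hi = r$value_hi, n_anchors = r$n_anchors
    )
  }))

  transactions <- vector("list", length(genes))
  for (i in seq_along(item_genes)) {
    for (g in item_genes[[i]]) transactions[[g]] <- c(transactions[[g]], i)
  }
  names(transactions) <- genes

  structure(
    list(
      items = items,
      column_stats = dplyr::bind_rows(stats_rows),
      gene_ids = genes, condition_ids = conds,
      item_genes = item_genes, transactions = transactions,
      clipped = clipped
    ),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf(
    "<transaction_db> %d items over %d/%d conditions, %d genes\n",
    nrow(x$items), length(unique(x$items$condition)),
    length(x$condition_ids), length(x$gene_ids)
  ))
  invisible(x)
}

# Dedup note: consecutive anchors with identical member runs collapse; the
# sort is by (value, gene index), so equal-valued genes always co-occur and
# the collapsed key comparison only needs the previous item (runs are
# nested intervals of a sorted list; identical sets are adjacent).

#' Dump the item matrix for debugging
#'
#' Writes a gene x condition TSV whose cells are comma-joined item ids
#' (empty where a gene is filtered out of a column).
#'
#' @param db a `transaction_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_item_matrix <- function(db, path) {
  cond_of <- db$items$condition
  cells <- matrix("", length(db$gene_ids), length(db$condition_ids),
                  dimnames = list(db$gene_ids, db$condition_ids))
  for (i in seq_along(db$item_genes)) {
    cj <- cond_of[i]
    for (g in db$item_genes[[i]]) {
      cur <- cells[g, cj]
      cells[g, cj] <- if (nzchar(cur)) paste0(cur, ",", i) else as.character(i)
    }
  }
  df <- dplyr::bind_cols(tibble::tibble(gene = db$gene_ids),
                         tibble::as_tibble(cells))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
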