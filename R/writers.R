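#' Write biclusters as tab-separated text
#'
#' One record per bicluster: comma-joined gene list, comma-joined
#' condition list, gene count, condition count, size (cell count), T
#' statistic and empirical p-value.  `by_size` orders by cell count
#' descending (ties: p ascending, then lexicographically smallest gene
#' id); `by_pvalue` orders by p ascending with the same tie-break and
#' requires scored biclusters.
#'
#' @param biclusters bicluster tibble.
#' @param path output TSV path.
#' @param order `"by_size"` or `"by_pvalue"`.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(biclusters, path, order = c("by_size", "by_pvalue")) {
  order <- match.arg(order)
  if (order == "by_pvalue" && nrow(biclusters) > 0 && anyNA(biclusters$p_value)) {
    stop("order = 'by_pvalue' requires scored biclusters", call. = FALSE)
  }
  b <- biclusters[order_biclusters(biclusters,
                                   if (order == "by_size") "size" else "p_value"), ]
  flat <- tibble::tibble(
    genes = vapply(b$genes, set_key, ""),
    conditions = vapply(b$conditions, set_key, ""),
    n_genes = b$n_genes, n_conditions = b$n_conditions, size = b$size,
    t_stat = b$t_stat, p_value = b$p_value
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Write biclusters as JSON lines
#'
#' One JSON object per line with fields genes, conditions, n_genes,
#' n_conditions, size, t_stat, p_value.
#'
#' @inheritParams write_biclusters
#' @return `path`, invisibly.
#' @export
write_biclusters_jsonl <- function(biclusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(biclusters))) {
    rec <- list(
      genes = biclusters$genes[[i]], conditions = biclusters$conditions[[i]],
      n_genes = biclusters$n_genes[i], n_conditions = biclusters$n_conditions[i],
      size = biclusters$size[i], t_stat = biclusters$t_stat[i],
      p_value = biclusters$p_value[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read biclusters from JSON lines
#'
#' Inverse of [write_biclusters_jsonl()].
#'
#' @param path JSON-lines path.
#' @return bicluster tibble.
#' @export
read_biclusters_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(empty_biclusters())
  rows <- lapply(lines, jsonlite::fromJSON)
  b <- new_biclusters(
    genes = lapply(rows, `[[`, "genes"),
    conditions = lapply(rows, `[[`, "conditions")
  )
  b$t_stat <- vapply(rows, function(r) r$t_stat %||% NA_real_, 0)
  b$p_value <- vapply(rows, function(r) r$p_value %||% NA_real_, 0)
  b
}
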