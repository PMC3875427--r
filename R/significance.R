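# Empirical significance of biclusters: average pairwise Pearson
# correlation of the row vectors, compared against same-shape submatrices
# sampled at random from the full matrix.

#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson coefficient; if either vector is constant the
#' correlation is defined as 0 (neutral) rather than NA.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: length mismatch", call. = FALSE)
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Coherence statistic of a bicluster
#'
#' The average Pearson correlation over all unordered pairs of row
#' vectors: `T = 2 / (R (R - 1)) * sum_{i < j} r(x_i, x_j)`.  The scale is
#' shape-invariant in \[-1, 1\], so biclusters of different sizes are
#' comparable.  Zero-variance rows contribute r = 0 to each of their pairs.
#'
#' @param rows numeric matrix, R >= 2 rows (genes) by C >= 2 columns.
#' @return the statistic T.
#' @examples
#' t_statistic(matrix(rnorm(20), 4, 5))
#' @export
t_statistic <- function(rows) {
  if (!is.matrix(rows) || nrow(rows) < 2) {
    stop("t_statistic: need a matrix with at least 2 rows", call. = FALSE)
  }
  if (ncol(rows) < 2) stop("t_statistic: need at least 2 columns", call. = FALSE)
  R <- nrow(rows); C <- ncol(rows)
  mu <- rowMeans(rows)
  s <- sqrt(rowMeans(rows^2) - mu^2)    # population SD per row
  z <- (rows - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0                      # constant rows: r = 0 with everything
  cs <- colSums(z)
  pair_dot <- (sum(cs^2) - sum(z^2)) / 2   # sum over i<j of z_i . z_j
  (pair_dot / C) * 2 / (R * (R - 1))
}

#' Null distribution cache for empirical p-values
#'
#' Creates a per-run cache of null T samples.  For each bicluster shape
#' (R genes, C conditions) the null is formed by drawing `n_perm`
#' submatrices of the full matrix: R distinct rows and C distinct columns
#' sampled uniformly and independently, non-contiguously.  Each shape's
#' sampling stream is seeded deterministically from the run seed and the
#' shape, so two biclusters of the same shape in one run share one null
#' ensemble and regeneration is order-independent.
#'
#' @param mat the full expression matrix.
#' @param rng_seed integer run seed.
#' @return An object of class `null_cache`.
#' @export
null_cache <- function(mat, rng_seed = 1) {
  mat <- validate_expression_matrix(mat)
  structure(
    list(mat = mat, rng_seed = as.integer(rng_seed), store = new.env(parent = emptyenv())),
    class = "null_cache"
  )
}

#' Null T samples for one bicluster shape
#'
#' @param cache a [null_cache()].
#' @param n_rows,n_cols the bicluster shape.
#' @param n_perm number of null draws.
#' @return numeric vector of `n_perm` null T values (cached).
#' @export
null_t_samples <- function(cache, n_rows, n_cols, n_perm) {
  stopifnot(inherits(cache, "null_cache"), n_perm >= 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows > nrow(cache$mat) || n_cols > ncol(cache$mat)) {
    stop("bicluster shape exceeds matrix dimensions", call. = FALSE)
  }
  key <- paste(n_rows, n_cols, n_perm, sep = "_")
  got <- get0(key, envir = cache$store, inherits = FALSE)
  if (!is.null(got)) return(got)
  seed_tag <- derive_seed(cache$rng_seed, 101L, n_rows, n_cols, n_perm)
  mat <- cache$mat
  NR <- nrow(mat); NC <- ncol(mat)
  samples <- with_seed(seed_tag, {
    vapply(seq_len(n_perm), function(k) {
      t_statistic(mat[sample.int(NR, n_rows), sample.int(NC, n_cols), drop = FALSE])
    }, 0)
  })
  assign(key, samples, envir = cache$store)
  samples
}

#' Empirical upper-tail p-value of a bicluster
#'
#' `p = (# null T >= observed T) / n_perm`: the fraction of random
#' same-shape submatrices at least as internally correlated as the
#' bicluster.  The minimum attainable p is 0 (no smoothing).
#'
#' @param genes,conditions character vectors naming the bicluster's rows
#'   and columns in `cache$mat`.
#' @param cache a [null_cache()] built on the full matrix.
#' @param n_perm number of null draws.
#' @return list with `t_stat` and `p_value`.
#' @export
empirical_pvalue <- function(genes, conditions, cache, n_perm) {
  stopifnot(n_perm >= 1)
  obs <- t_statistic(cache$mat[genes, conditions, drop = FALSE])
  nulls <- null_t_samples(cache, length(genes), length(conditions), n_perm)
  list(t_stat = obs, p_value = mean(nulls >= obs))
}

#' Score a table of biclusters
#'
#' Fills `t_stat` and `p_value` for every bicluster, reusing one null
#' ensemble per shape through the cache.
#'
#' @param biclusters a bicluster tibble (see [itemsets_to_biclusters()]).
#' @param cache a [null_cache()].
#' @param n_perm permutations per shape.
#' @return the tibble with `t_stat`, `p_value` filled.
#' @export
score_biclusters <- function(biclusters, cache, n_perm) {
  if (nrow(biclusters) == 0) return(biclusters)
  for (i in seq_len(nrow(biclusters))) {
    sc <- empirical_pvalue(biclusters$genes[[i]], biclusters$conditions[[i]], cache, n_perm)
    biclusters$t_stat[i] <- sc$t_stat
    biclusters$p_value[i] <- sc$p_value
  }
  biclusters
}

#' Keep significant biclusters, sorted by p-value
#'
#' @param biclusters scored bicluster tibble.
#' @param alpha significance level; biclusters with `p_value <= alpha` kept.
#' @return filtered tibble, p ascending with the global tie-break.
#' @export
filter_significant <- function(biclusters, alpha) {
  if (nrow(biclusters) == 0) return(biclusters)
  if (anyNA(biclusters$p_value)) stop("filter_significant: unscored biclusters", call. = FALSE)
  b <- biclusters[biclusters$p_value <= alpha, ]
  b[order_biclusters(b, "p_value"), ]
}

#' Remove heavily overlapped smaller biclusters
#'
#' Evaluation-style redundancy filter: processing biclusters from largest
#' to smallest (cell count), a bicluster is removed if more than 50% of its
#' cells (gene x condition pairs) are covered by an already-kept larger
#' bicluster.  Overlap of exactly one half is kept (the rule is strict).
#'
#' @param biclusters bicluster tibble.
#' @param max_overlap overlap fraction above which the smaller is dropped.
#' @return filtered tibble, size descending.
#' @export
overlap_filter <- function(biclusters, max_overlap = 0.5) {
  if (nrow(biclusters) <= 1) return(biclusters)
  b <- biclusters[order_biclusters(biclusters, "size"), ]
  kept <- integer()
  for (i in seq_len(nrow(b))) {
    drop <- FALSE
    for (k in kept) {
      shared <- length(intersect(b$genes[[i]], b$genes[[k]])) *
        length(intersect(b$conditions[[i]], b$conditions[[k]]))
      if (shared / b$size[i] > max_overlap) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  b[kept, ]
}

#' Largest k biclusters by cell count
#'
#' @param biclusters bicluster tibble.
#' @param k how many to keep (>= 0).
#' @return first `k` biclusters under size-descending order with the
#'   global tie-break.
#' @export
top_k_by_size <- function(biclusters, k) {
  stopifnot(k >= 0)
  b <- biclusters[order_biclusters(biclusters, "size"), ]
  utils::head(b, k)
}

#' Dump null T samples for audit
#'
#' @param cache a [null_cache()] that has been used for scoring.
#' @param path output TSV path (shape, draw index, T).
#' @return `path`, invisibly.
#' @export
write_null_samples <- function(cache, path) {
  keys <- sort(ls(cache$store))
  rows <- lapply(keys, function(k) {
    tibble::tibble(shape = k, draw = seq_along(cache$store[[k]]), t = cache$store[[k]])
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
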