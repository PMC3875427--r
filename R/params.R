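#' Parameters for the biclustering pipeline
#'
#' Bundles every tunable of the pipeline. `bin` controls the per-column
#' window width: each column is clipped into Mean +/- 3 SD, so the coherence
#' width is `MAX_DIFF = 6 * SD / bin`.  `sd_coeff` removes weakly
#' differentiated values (within `sd_coeff * SD` of the column mean) before
#' items are formed.  `min_row` / `min_col` are the minimum gene and
#' condition counts of a reported bicluster.  `n_perm` is the number of
#' random same-shape submatrices drawn for each empirical p-value;
#' `n_perm_merge` is the cheaper permutation count used inside the merge
#' binary search (final merged biclusters are rescored at `n_perm`).
#'
#' @param min_row minimum number of genes in a bicluster (>= 2).
#' @param min_col minimum number of conditions in a bicluster (>= 2).
#' @param bin positive integer; window width is `6 * SD / bin` per column.
#' @param sd_coeff non-negative; values within `sd_coeff * SD` of the column
#'   mean are dropped before item generation.
#' @param alpha significance level in (0, 1] applied to empirical p-values.
#' @param n_perm permutations per null distribution (>= 1).
#' @param n_perm_merge permutations used inside the merge search; capped at
#'   `n_perm`.
#' @param rng_seed integer seed; all randomness in a run derives from it.
#' @return An object of class `fimbic_params` (a named list).
#' @examples
#' fimbic_params(min_row = 10, n_perm = 1000)
#' @export
fimbic_params <- function(min_row = 30, min_col = 3, bin = 7, sd_coeff = 0.7,
                          alpha = 0.05, n_perm = 100000,
                          n_perm_merge = 10000, rng_seed = 1) {
  stopifnot(
    min_row >= 2, min_col >= 2, bin >= 1, sd_coeff >= 0,
    alpha > 0, alpha <= 1, n_perm >= 1, n_perm_merge >= 1
  )
  p <- list(
    min_row = as.integer(min_row), min_col = as.integer(min_col),
    bin = as.integer(bin), sd_coeff = as.double(sd_coeff),
    alpha = as.double(alpha), n_perm = as.integer(n_perm),
    n_perm_merge = as.integer(min(n_perm_merge, n_perm)),
    rng_seed = as.integer(rng_seed)
  )
  structure(p, class = "fimbic_params")
}

#' @export
print.fimbic_params <- function(x, ...) {
  cat("<fimbic_params>\n")
  cat(sprintf(
    "  min_row=%d min_col=%d bin=%d sd_coeff=%g\n  alpha=%g n_perm=%d n_perm_merge=%d rng_seed=%d\n",
    x$min_row, x$min_col, x$bin, x$sd_coeff, x$alpha, x$n_perm,
    x$n_perm_merge, x$rng_seed
  ))
  invisible(x)
}
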