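# Synthetic expression matrices with implanted coherent-column biclusters
# and ground truth, for tests and demos.

#' Describe one implanted bicluster block
#'
#' @param genes integer row indices of the block.
#' @param conditions integer column indices of the block.
#' @param level per-condition center expression of the block; one value per
#'   condition (recycled if scalar).  The default (`NULL`) spaces the
#'   levels evenly over 2 to 3.5 background SDs: far enough from the
#'   column mean that the weak-signal filter at its default (0.7) retains
#'   the block cells, and varying across conditions so the block rows
#'   share a strong common profile (coherent direction, differing
#'   magnitude), as row-correlation scoring expects.
#' @param jitter total within-column spread: block cells are
#'   `level + U(-jitter/2, +jitter/2)`, so the per-column range is at most
#'   `jitter` and coherence under the intended window width is guaranteed
#'   by choosing `jitter <= 6 * SD / bin`.
#' @return a list describing the block.
#' @export
implant_block <- function(genes, conditions, level = NULL, jitter = 0.3) {
  stopifnot(length(genes) >= 1, length(conditions) >= 1, jitter >= 0)
  if (is.null(level)) {
    level <- if (length(conditions) == 1) 2
             else seq(2, 3.5, length.out = length(conditions))
  }
  level <- rep_len(level, length(conditions))
  list(genes = sort(as.integer(genes)), conditions = sort(as.integer(conditions)),
       level = level, jitter = jitter)
}

#' Simulate an expression matrix with implanted biclusters
#'
#' Background cells are independent draws from `N(0, noise_sd^2)`; each
#' block's cells are overwritten by its per-condition level plus uniform
#' jitter.  After generation the per-column window width
#' `MAX_DIFF = 6 * SD / bin` is computed on the finished matrix and every
#' block is checked to span at most MAX_DIFF within each of its columns
#' (error if not): implanted truth is guaranteed coherent under `bin`.
#'
#' @param n_genes,n_conditions matrix shape.
#' @param blocks list of [implant_block()] specs (may be empty).
#' @param noise_sd background standard deviation.
#' @param bin intended bin count for the coherence check.
#' @param seed integer seed; fixed seed gives an identical matrix.
#' @param allow_overlap set `TRUE` to permit blocks sharing cells
#'   (later blocks overwrite earlier ones).
#' @return list with `matrix` (genes x conditions, named g1.., c1..) and
#'   `truth` (tibble: block, genes, conditions list-columns with
#'   identifiers), class `implant_sim`.
#' @examples
#' sim <- simulate_expression(50, 8, list(implant_block(1:10, 1:4)), seed = 1)
#' sim$truth
#' @export
simulate_expression <- function(n_genes, n_conditions, blocks = list(),
                                noise_sd = 1, bin = 7, seed = 1,
                                allow_overlap = FALSE) {
  stopifnot(n_genes >= 2, n_conditions >= 2, noise_sd > 0)
  genes <- paste0("g", seq_len(n_genes))
  conds <- paste0("c", seq_len(n_conditions))
  mat <- with_seed(derive_seed(seed, 7L), {
    m <- matrix(stats::rnorm(n_genes * n_conditions, sd = noise_sd),
                n_genes, n_conditions, dimnames = list(genes, conds))
    taken <- matrix(FALSE, n_genes, n_conditions)
    for (blk in blocks) {
      stopifnot(max(blk$genes) <= n_genes, max(blk$conditions) <= n_conditions)
      cells <- cbind(rep(blk$genes, length(blk$conditions)),
                     rep(blk$conditions, each = length(blk$genes)))
      if (!allow_overlap && any(taken[cells])) {
        stop("implanted blocks overlap; set allow_overlap = TRUE", call. = FALSE)
      }
      taken[cells] <- TRUE
      for (ci in seq_along(blk$conditions)) {
        m[blk$genes, blk$conditions[ci]] <- blk$level[ci] +
          stats::runif(length(blk$genes), -blk$jitter / 2, blk$jitter / 2)
      }
    }
    m
  })
  # coherence guarantee under the intended bin
  for (bi in seq_along(blocks)) {
    blk <- blocks[[bi]]
    for (j in blk$conditions) {
      cl <- clip_outliers(mat[, j])
      md <- max_diff(cl$sd, bin)
      spread <- diff(range(cl$values[blk$genes]))
      if (spread > md + 1e-12) {
        stop(sprintf("block %d spans %.3f > MAX_DIFF %.3f in column %s; reduce jitter",
                     bi, spread, md, conds[j]), call. = FALSE)
      }
    }
  }
  truth <- dplyr::bind_rows(lapply(seq_along(blocks), function(bi) {
    tibble::tibble(block = bi,
                   genes = list(genes[blocks[[bi]]$genes]),
                   conditions = list(conds[blocks[[bi]]$conditions]))
  }))
  structure(list(matrix = mat, truth = truth), class = "implant_sim")
}

#' @export
print.implant_sim <- function(x, ...) {
  cat(sprintf("<implant_sim> %d x %d matrix, %d implanted block(s)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$truth)))
  invisible(x)
}

#' Score recovery of implanted blocks
#'
#' For each ground-truth block, the best-matching found bicluster by shared
#' cell count (gene x condition pairs) determines the block's gene recall,
#' condition recall and gene precision.
#'
#' @param found bicluster tibble.
#' @param truth the `truth` tibble of an [simulate_expression()] result.
#' @return tibble (block, gene_recall, condition_recall, gene_precision,
#'   best_match row index or NA).
#' @export
score_recovery <- function(found, truth) {
  dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(ti) {
    tg <- truth$genes[[ti]]; tc <- truth$conditions[[ti]]
    if (nrow(found) == 0) {
      return(tibble::tibble(block = truth$block[ti], gene_recall = 0,
                            condition_recall = 0, gene_precision = NA_real_,
                            best_match = NA_integer_))
    }
    shared <- vapply(seq_len(nrow(found)), function(fi) {
      length(intersect(found$genes[[fi]], tg)) *
        length(intersect(found$conditions[[fi]], tc))
    }, 0)
    best <- which.max(shared)
    tibble::tibble(
      block = truth$block[ti],
      gene_recall = length(intersect(found$genes[[best]], tg)) / length(tg),
      condition_recall = length(intersect(found$conditions[[best]], tc)) / length(tc),
      gene_precision = length(intersect(found$genes[[best]], tg)) / length(found$genes[[best]]),
      best_match = as.integer(best)
    )
  }))
}
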