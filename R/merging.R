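# Merge overlapping biclusters that share an identical condition set into
# larger biclusters while keeping the empirical p-value under alpha.

#' Partition biclusters into merge groups
#'
#' Biclusters are grouped when they have exactly the same condition set and
#' are connected through gene overlap (connected components of the
#' share-a-gene relation within each condition-set partition).  Singleton
#' components form singleton groups.
#'
#' @param biclusters scored bicluster tibble.
#' @return A list of integer vectors: row indices into `biclusters`, one
#'   per merge group, in deterministic order.
#' @export
build_merge_groups <- function(biclusters) {
  n <- nrow(biclusters)
  if (n == 0) return(list())
  cond_key <- vapply(biclusters$conditions, set_key, "")
  groups <- list()
  for (ck in sort(unique(cond_key))) {
    idx <- which(cond_key == ck)
    # union-find over gene overlap
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        if (length(intersect(biclusters$genes[[idx[a]]], biclusters$genes[[idx[b]]])) > 0) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(seq_along(idx), find, 0L)
    for (r in sort(unique(roots))) {
      groups[[length(groups) + 1L]] <- idx[roots == r]
    }
  }
  groups
}

#' Merge one group of biclusters
#'
#' Seed = the member with the smallest p-value (global tie-break).  The
#' seed centroid is the per-condition mean expression of the seed genes
#' over the group's conditions.  Candidate genes (the group's gene union
#' minus the seed genes) are ranked by descending Pearson correlation with
#' the centroid, restricted to the group's conditions, and a binary search
#' over prefix lengths finds the largest prefix whose merged bicluster
#' still has empirical p <= alpha (evaluated at the cheaper
#' `n_perm_merge`).  The merged bicluster is rescored at the full `n_perm`;
#' if the rescored p exceeds alpha the prefix is shortened until it does
#' not (the seed itself always qualifies).
#'
#' The significance predicate need not be monotone in the prefix length;
#' the binary search then returns a feasible, not necessarily largest,
#' prefix (it agrees with an exhaustive scan whenever the predicate is
#' monotone).
#'
#' @param group integer row indices into `biclusters` (one merge group).
#' @param biclusters the scored bicluster tibble.
#' @param cache a [null_cache()] on the full matrix.
#' @param params a [fimbic_params()].
#' @return A one-row bicluster tibble.
#' @export
merge_group <- function(group, biclusters, cache, params) {
  members <- biclusters[group, ]
  seed_i <- order_biclusters(members, "p_value")[1]
  seed <- members[seed_i, ]
  if (nrow(members) == 1) return(seed)
  conds <- seed$conditions[[1]]
  union_genes <- sort(unique(unlist(members$genes)))
  candidates <- setdiff(union_genes, seed$genes[[1]])
  if (length(candidates) == 0) return(seed)

  centroid <- colMeans(cache$mat[seed$genes[[1]], conds, drop = FALSE])
  r <- vapply(candidates, function(g) pearson_r(cache$mat[g, conds], centroid), 0)
  candidates <- candidates[order(-r, candidates)]

  sig_at <- function(k) {
    g <- c(seed$genes[[1]], candidates[seq_len(k)])
    empirical_pvalue(g, conds, cache, params$n_perm_merge)$p_value <= params$alpha
  }
  lo <- 0L; hi <- length(candidates)
  while (lo < hi) {
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (sig_at(mid)) lo <- mid else hi <- mid - 1L
  }
  k <- lo
  while (k > 0L) {
    g <- sort(c(seed$genes[[1]], candidates[seq_len(k)]))
    sc <- empirical_pvalue(g, conds, cache, params$n_perm)
    if (sc$p_value <= params$alpha) {
      out <- new_biclusters(list(g), list(conds), sc$t_stat, sc$p_value)
      return(out)
    }
    k <- k - 1L
  }
  seed
}

#' Merge all biclusters
#'
#' One merged bicluster per merge group; results deduplicated on
#' (genes, conditions).  Every output satisfies p <= alpha and the output
#' never has more biclusters than the input.  Applying the operation twice
#' changes nothing: merged groups have pairwise-disjoint gene sets within
#' each condition-set partition, so they re-partition into singletons.
#'
#' @param biclusters scored, alpha-filtered bicluster tibble.
#' @param cache a [null_cache()] on the full matrix.
#' @param params a [fimbic_params()].
#' @return merged bicluster tibble, size descending.
#' @export
merge_all <- function(biclusters, cache, params) {
  if (nrow(biclusters) == 0) return(biclusters)
  groups <- build_merge_groups(biclusters)
  merged <- dplyr::bind_rows(lapply(groups, merge_group,
                                    biclusters = biclusters,
                                    cache = cache, params = params))
  key <- paste(vapply(merged$genes, set_key, ""),
               vapply(merged$conditions, set_key, ""), sep = "|")
  merged <- merged[!duplicated(key), ]
  merged[order_biclusters(merged, "size"), ]
}

#' Merge provenance table
#'
#' For reporting: which input biclusters formed each merge group.
#'
#' @param biclusters the scored input tibble.
#' @return tibble (group, member, n_genes, n_conditions, p_value).
#' @export
merge_provenance <- function(biclusters) {
  groups <- build_merge_groups(biclusters)
  dplyr::bind_rows(lapply(seq_along(groups), function(gi) {
    idx <- groups[[gi]]
    tibble::tibble(
      group = gi, member = idx,
      n_genes = biclusters$n_genes[idx],
      n_conditions = biclusters$n_conditions[idx],
      p_value = biclusters$p_value[idx]
    )
  }))
}
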