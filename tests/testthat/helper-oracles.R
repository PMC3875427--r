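# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately use naive enumeration / literal double loops so they
# stay independent of the implementation paths they check.

# Average pairwise Pearson correlation by literal double loop.
oracle_t <- function(m) {
  R <- nrow(m)
  acc <- 0
  for (i in seq_len(R - 1)) {
    for (j in seq(i + 1, R)) {
      sx <- stats::sd(m[i, ]); sy <- stats::sd(m[j, ])
      acc <- acc + if (sx == 0 || sy == 0) 0 else stats::cor(m[i, ], m[j, ])
    }
  }
  2 * acc / (R * (R - 1))
}

# Brute-force maximal frequent itemsets over all item subsets (<= 18 items).
# item_genes: list of integer vectors.  Returns list of sorted item-id sets.
oracle_mfi <- function(item_genes, min_row) {
  n <- length(item_genes)
  stopifnot(n >= 1, n <= 18)
  freq <- list()
  for (mask in seq_len(2^n - 1)) {
    ids <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    sup <- Reduce(intersect, item_genes[ids])
    if (length(sup) >= min_row) freq[[length(freq) + 1L]] <- ids
  }
  keep <- rep(TRUE, length(freq))
  for (i in seq_along(freq)) {
    for (k in seq_along(freq)) {
      if (i != k && length(freq[[k]]) > length(freq[[i]]) &&
          all(freq[[i]] %in% freq[[k]])) { keep[i] <- FALSE; break }
    }
  }
  freq[keep]
}

# Exhaustive maximal coherent submatrices by gene-subset enumeration
# (<= 12 genes): a (G, C) pair is coherent when every gene of G survives
# the weak-signal filter in every column of C and the clipped values of G
# span at most that column's MAX_DIFF.  Returns "genes|conds" keys of the
# maximal pairs with |G| >= min_row, |C| >= min_col.
oracle_max_biclusters <- function(mat, bin, sd_coeff, min_row, min_col) {
  ng <- nrow(mat); nc <- ncol(mat)
  stopifnot(ng <= 12)
  cl <- mat; ret <- matrix(FALSE, ng, nc); md <- numeric(nc)
  for (j in seq_len(nc)) {
    x <- mat[, j]; m <- mean(x); s <- sqrt(mean((x - m)^2))
    if (s == 0) next
    cl[, j] <- pmin(pmax(x, m - 3 * s), m + 3 * s)
    md[j] <- 6 * s / bin
    ret[, j] <- abs(cl[, j] - m) >= sd_coeff * s
  }
  out <- list()
  for (mask in seq_len(2^ng - 1)) {
    G <- which(bitwAnd(mask, bitwShiftL(1L, 0:(ng - 1))) != 0L)
    if (length(G) < min_row) next
    C <- which(vapply(seq_len(nc), function(j) {
      s_ok <- md[j] > 0 && all(ret[G, j])
      s_ok && (max(cl[G, j]) - min(cl[G, j])) <= md[j]
    }, TRUE))
    if (length(C) >= min_col) out[[length(out) + 1L]] <- list(genes = G, conds = C)
  }
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    for (k in seq_along(out)) {
      if (i == k) next
      if (all(out[[i]]$genes %in% out[[k]]$genes) &&
          all(out[[i]]$conds %in% out[[k]]$conds) &&
          (length(out[[k]]$genes) > length(out[[i]]$genes) ||
           length(out[[k]]$conds) > length(out[[i]]$conds))) { keep[i] <- FALSE; break }
    }
  }
  vapply(out[keep], function(b) {
    paste(paste(rownames(mat)[b$genes], collapse = ","),
          paste(colnames(mat)[b$conds], collapse = ","), sep = "|")
  }, "")
}

# Per-gene signature tally: the reference construction of gene set nodes
# and edge weights, independent of build_network().
oracle_network <- function(biclusters) {
  sig <- list()
  for (b in seq_len(nrow(biclusters))) {
    for (g in biclusters$genes[[b]]) sig[[g]] <- c(sig[[g]], b)
  }
  keys <- vapply(sig, function(s) paste(sort(s), collapse = ","), "")
  nodes <- lapply(sort(unique(keys)), function(k) sort(names(sig)[keys == k]))
  sigs <- lapply(sort(unique(keys)), function(k) as.integer(strsplit(k, ",")[[1]]))
  w <- list()
  if (length(nodes) > 1) {
    for (a in seq_len(length(nodes) - 1)) {
      for (b in seq(a + 1, length(nodes))) {
        ww <- length(intersect(sigs[[a]], sigs[[b]]))
        if (ww >= 1) w[[paste(a, b)]] <- ww
      }
    }
  }
  list(nodes = nodes, signatures = sigs, weights = w)
}

# Minimal transaction_db for driving the miner directly with hand-built
# items (bypasses preprocessing).
fake_db <- function(item_genes, conditions, n_genes) {
  gene_ids <- paste0("g", seq_len(n_genes))
  items <- tibble::tibble(
    item_id = seq_along(item_genes),
    condition = conditions,
    genes = lapply(item_genes, function(ix) sort(gene_ids[ix])),
    value_lo = NA_real_, value_hi = NA_real_, n_anchors = 1L
  )
  structure(
    list(items = items, column_stats = tibble::tibble(),
         gene_ids = gene_ids, condition_ids = sort(unique(conditions)),
         item_genes = lapply(item_genes, function(ix) sort(as.integer(ix))),
         transactions = NULL, clipped = NULL),
    class = "transaction_db"
  )
}

# Bicluster tibble from plain lists (ids as character).
make_bics <- function(genes, conditions, p = NA_real_, t = NA_real_) {
  b <- fimbic:::new_biclusters(genes, conditions)
  b$p_value <- rep_len(p, nrow(b))
  b$t_stat <- rep_len(t, nrow(b))
  b
}

# The worked three-bicluster configuration: five gene groups s1..s5 with
# membership signatures {B1}, {B1,B2}, {B1,B2,B3}, {B2,B3}, {B3}.
fig_config_biclusters <- function(genes_per_set = 2) {
  s <- lapply(1:5, function(k) paste0("s", k, "_", seq_len(genes_per_set)))
  make_bics(
    genes = list(c(s[[1]], s[[2]], s[[3]]),
                 c(s[[2]], s[[3]], s[[4]]),
                 c(s[[3]], s[[4]], s[[5]])),
    conditions = list(c("c1", "c2", "c3"), c("c4", "c5", "c6"), c("c7", "c8", "c9")),
    p = 0, t = 1
  )
}

random_matrix <- function(ng, nc, seed) {
  set.seed(seed)
  matrix(stats::rnorm(ng * nc), ng, nc,
         dimnames = list(paste0("g", seq_len(ng)), paste0("c", seq_len(nc))))
}
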