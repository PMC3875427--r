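test_that("merge groups partition by condition set and gene-overlap connectivity", {
  b <- make_bics(
    genes = list(c("g1", "g2", "g3"), c("g3", "g4"), c("g4", "g5"), c("g8", "g9"),
                 c("g1", "g2")),
    conditions = list(c("c1", "c2"), c("c1", "c2"), c("c1", "c2"), c("c1", "c2"),
                      c("c3", "c4")),
    p = c(0.01, 0.02, 0.03, 0.04, 0.05)
  )
  groups <- build_merge_groups(b)
  sets <- lapply(groups, sort)
  # chain 1-2-3 despite bicluster 1 and 3 sharing no gene; 4 disjoint; 5 other conds
  expect_true(list(c(1L, 2L, 3L)) %in% sets)
  expect_true(list(4L) %in% sets)
  expect_true(list(5L) %in% sets)
  expect_length(groups, 3)

  distinct <- make_bics(list(c("g1", "g2"), c("g1", "g2")),
                        list(c("c1", "c2"), c("c2", "c3")), p = 0)
  expect_length(build_merge_groups(distinct), 2)
})

test_that("a singleton group returns its bicluster unchanged", {
  sim <- simulate_expression(40, 6, list(implant_block(1:8, 1:3)), seed = 4)
  cache <- null_cache(sim$matrix, 1)
  p <- fimbic_params(min_row = 5, n_perm = 100)
  b <- score_biclusters(make_bics(list(paste0("g", 1:8)), list(paste0("c", 1:3))), cache, 100)
  out <- merge_group(1L, b, cache, p)
  expect_identical(out$genes, b$genes)
  expect_identical(out$p_value, b$p_value)
})

test_that("an implanted block split into overlapping halves is reassembled", {
  sim <- simulate_expression(80, 8, list(implant_block(1:12, 1:4)), seed = 5)
  cache <- null_cache(sim$matrix, 3)
  p <- fimbic_params(min_row = 5, alpha = 0.05, n_perm = 400, n_perm_merge = 400)
  halves <- make_bics(
    genes = list(paste0("g", 1:8), paste0("g", 5:12)),
    conditions = rep(list(paste0("c", 1:4)), 2)
  )
  halves <- score_biclusters(halves, cache, p$n_perm)
  merged <- merge_all(halves, cache, p)
  expect_equal(nrow(merged), 1)
  expect_setequal(merged$genes[[1]], paste0("g", 1:12))
  expect_lte(merged$p_value, p$alpha)

  # binary search agrees with an exhaustive prefix scan when the
  # significance predicate is monotone in the prefix length
  seed_b <- halves[which.min(halves$p_value), ]
  cands <- setdiff(paste0("g", 1:12), seed_b$genes[[1]])
  centroid <- colMeans(sim$matrix[seed_b$genes[[1]], paste0("c", 1:4)])
  r <- vapply(cands, function(g) pearson_r(sim$matrix[g, paste0("c", 1:4)], centroid), 0)
  cands <- cands[order(-r, cands)]
  feasible <- vapply(seq_along(cands), function(k) {
    empirical_pvalue(c(seed_b$genes[[1]], cands[seq_len(k)]),
                     paste0("c", 1:4), cache, p$n_perm_merge)$p_value <= p$alpha
  }, TRUE)
  expect_true(all(feasible))          # monotone (all TRUE) in this fixture
  expect_equal(merged$n_genes, length(seed_b$genes[[1]]) + max(which(feasible)))
})

test_that("candidates that destroy significance are refused (seed returned)", {
  # alpha so strict that only p = 0 passes; anti-correlated candidate drops
  # the observed T below some null draws, so every prefix fails
  blocks <- list(implant_block(1:5, 1:4),
                 implant_block(6:7, 1:4, level = c(3.5, 2.5, 1.5, 1)))
  sim <- simulate_expression(60, 8, blocks, seed = 6, allow_overlap = FALSE)
  cache <- null_cache(sim$matrix, 2)
  p <- fimbic_params(min_row = 3, alpha = 1e-9, n_perm = 300, n_perm_merge = 300)
  b <- make_bics(
    genes = list(paste0("g", 1:5), c("g1", "g6", "g7")),
    conditions = rep(list(paste0("c", 1:4)), 2)
  )
  b <- score_biclusters(b, cache, p$n_perm)
  expect_equal(b$p_value[1], 0)       # seed alone is maximally significant
  merged <- merge_group(1:2, b, cache, p)
  linear_best <- {
    seed_g <- paste0("g", 1:5)
    cands <- c("g6", "g7")
    ok <- vapply(1:2, function(k) {
      empirical_pvalue(c(seed_g, cands[seq_len(k)]), paste0("c", 1:4),
                       cache, p$n_perm)$p_value <= p$alpha
    }, TRUE)
    if (any(ok)) max(which(ok)) else 0L
  }
  expect_equal(merged$n_genes, 5 + linear_best)
  expect_equal(linear_best, 0L)       # every prefix loses significance
  expect_identical(merged$genes, b$genes[1])
})

test_that("merge_all contracts: significance kept, count reduced, idempotent", {
  sim <- simulate_expression(100, 10, list(implant_block(1:14, 1:4)), seed = 7)
  cache <- null_cache(sim$matrix, 5)
  p <- fimbic_params(min_row = 5, n_perm = 300, n_perm_merge = 300)
  set.seed(8)
  # 30 random overlapping fragments of the implanted block
  frags <- lapply(1:30, function(i) sort(sample(paste0("g", 1:14), 7)))
  b <- score_biclusters(make_bics(frags, rep(list(paste0("c", 1:4)), 30)), cache, p$n_perm)
  b <- filter_significant(b, p$alpha)
  expect_gt(nrow(b), 0)
  merged <- merge_all(b, cache, p)
  expect_equal(nrow(merged), 1)
  expect_true(all(merged$p_value <= p$alpha))
  expect_lte(nrow(merged), nrow(b))
  again <- merge_all(merged, cache, p)
  expect_identical(again$genes, merged$genes)
  expect_identical(again$p_value, merged$p_value)

  # pairwise-unrelated biclusters pass through unchanged
  iso <- score_biclusters(make_bics(
    list(paste0("g", 20:26), paste0("g", 30:36)),
    list(paste0("c", 1:3), paste0("c", 5:7))
  ), cache, 300)
  out <- merge_all(iso, cache, p)
  expect_setequal(vapply(out$genes, paste, "", collapse = ","),
                  vapply(iso$genes, paste, "", collapse = ","))
})
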