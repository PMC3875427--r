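test_that("clipping leaves in-range columns unchanged and caps outliers at Mean+/-3SD", {
  x <- c(-1, 0, 0.5, 1)
  expect_identical(clip_outliers(x)$values, x)

  set.seed(7)
  y <- rnorm(50)
  y[17] <- 10
  # independent recomputation by direct summation on the ORIGINAL values
  m <- sum(y) / length(y)
  s <- sqrt(sum((y - m)^2) / length(y))
  cl <- clip_outliers(y)
  expect_equal(cl$mean, m)
  expect_equal(cl$sd, s)
  altered <- which(cl$values != y)
  expect_identical(altered, 17L)
  expect_equal(cl$values[17], m + 3 * s)
})

test_that("window width follows 6*SD/bin and vanishes for degenerate columns", {
  expect_equal(max_diff(sd = 7, bin = 7), 6)
  expect_equal(max_diff(sd = 0, bin = 5), 0)
  expect_equal(max_diff(sd = 1.4, bin = 7), 1.2)
})

test_that("weak-signal filter removes the band around the mean", {
  v <- c(-3, -1, 0, 1, 3)
  cl <- clip_outliers(v)
  expect_true(all(sd_filter(cl$values, cl$mean, cl$sd, 0)))
  # direct arithmetic: mean 0, population SD 2, band 0.7*2 = 1.4
  expect_equal(cl$sd, 2)
  expect_identical(sd_filter(cl$values, cl$mean, cl$sd, 0.7),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # a value exactly at the mean is always removed for positive sd_coeff
  expect_false(sd_filter(0, mean = 0, sd = 2, sd_coeff = 0.1))
})

test_that("items are closed windows over sorted retained genes, deduplicated", {
  # one informative column; second column constant-ish noise to satisfy shape
  set.seed(11)
  for (rep in 1:10) {
    m <- random_matrix(12, 4, seed = 100 + rep)
    db <- generate_items(m, fimbic_params(min_row = 2, bin = 4, sd_coeff = 0.3))
    # oracle: exhaustive window scan per column on clipped, filtered values
    for (j in colnames(m)) {
      cl <- clip_outliers(m[, j])
      md <- max_diff(cl$sd, 4)
      keep <- sd_filter(cl$values, cl$mean, cl$sd, 0.3)
      expected <- unique(lapply(which(keep), function(a) {
        sort(rownames(m)[keep & cl$values >= cl$values[a] &
                           cl$values <= cl$values[a] + md])
      }))
      got <- db$items$genes[db$items$condition == j]
      expect_setequal(lapply(got, identity), expected)
      # anchor multiplicity accounts for every retained gene
      expect_equal(sum(db$items$n_anchors[db$items$condition == j]), sum(keep))
    }
  }
})

test_that("equal-valued genes always co-occur and windows respect MAX_DIFF", {
  m <- matrix(c(1, 1, 2.5, 4, 4, 9,
                0, 1, 2, 3, 4, 5), 6, 2,
              dimnames = list(paste0("g", 1:6), c("c1", "c2")))
  db <- generate_items(m, fimbic_params(min_row = 2, bin = 3, sd_coeff = 0))
  c1 <- db$items[db$items$condition == "c1", ]
  for (i in seq_len(nrow(c1))) {
    g <- c1$genes[[i]]
    expect_true(xor("g1" %in% g, "g2" %in% g) == FALSE)  # together or absent
    expect_true(xor("g4" %in% g, "g5" %in% g) == FALSE)
  }
  # coherence: member values span at most the column MAX_DIFF
  st <- db$column_stats
  for (i in seq_len(nrow(db$items))) {
    mdj <- st$max_diff[st$condition == db$items$condition[i]]
    vals <- db$clipped[db$items$genes[[i]], db$items$condition[i]]
    expect_lte(diff(range(vals)), mdj + 1e-12)
  }
})

test_that("columns are independent and degenerate columns yield no items", {
  m <- random_matrix(10, 3, seed = 5)
  db1 <- generate_items(m, fimbic_params(min_row = 2))
  m2 <- m
  m2[, 3] <- m[sample(1:10), 3]       # permute another column
  db2 <- generate_items(m2, fimbic_params(min_row = 2))
  expect_identical(db1$items$genes[db1$items$condition == "c1"],
                   db2$items$genes[db2$items$condition == "c1"])

  m3 <- m
  m3[, 2] <- 1                         # zero-SD column
  db3 <- generate_items(m3, fimbic_params(min_row = 2))
  expect_false("c2" %in% db3$items$condition)
  expect_equal(db3$column_stats$n_retained[2], 0)

  m4 <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  expect_error(generate_items(m4, fimbic_params(min_row = 2)), "degenerate")
})

test_that("raising sd_coeff or bin never grows an item's gene set", {
  for (seed in 1:5) {
    m <- random_matrix(15, 4, seed = 200 + seed)
    loose <- generate_items(m, fimbic_params(min_row = 2, bin = 4, sd_coeff = 0.3))
    for (strict in list(fimbic_params(min_row = 2, bin = 8, sd_coeff = 0.3),
                        fimbic_params(min_row = 2, bin = 4, sd_coeff = 0.8))) {
      db <- generate_items(m, strict)
      for (i in seq_len(nrow(db$items))) {
        cond <- db$items$condition[i]
        peers <- loose$items$genes[loose$items$condition == cond]
        contained <- any(vapply(peers, function(p) all(db$items$genes[[i]] %in% p), TRUE))
        expect_true(contained)
      }
    }
  }
})
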