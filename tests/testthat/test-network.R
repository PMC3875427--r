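test_that("the worked three-bicluster configuration gives the expected network", {
  b <- fig_config_biclusters()
  nets <- build_network(b)
  expect_length(nets, 1)
  net <- nets[[1]]
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 7)
  # the {B1,B2} and {B1,B2,B3} nodes share two biclusters
  id12 <- net$nodes$node_id[vapply(net$nodes$signature, identical, TRUE, c(1L, 2L))]
  id123 <- net$nodes$node_id[vapply(net$nodes$signature, identical, TRUE, 1:3)]
  e <- net$edges[(net$edges$from == id12 & net$edges$to == id123) |
                 (net$edges$from == id123 & net$edges$to == id12), ]
  expect_equal(e$weight, 2)
  # node conditions are the union over the signature's biclusters
  expect_setequal(net$nodes$conditions[[which(net$nodes$node_id == id123)]],
                  paste0("c", 1:9))
})

test_that("a single bicluster yields one node and no edges", {
  nets <- build_network(make_bics(list(c("g1", "g2", "g3")), list(c("c1", "c2"))))
  expect_length(nets, 1)
  expect_equal(nrow(nets[[1]]$nodes), 1)
  expect_equal(nrow(nets[[1]]$edges), 0)
})

test_that("partition, clique and weight identities hold against the signature oracle", {
  set.seed(13)
  for (rep in 1:25) {
    n_b <- sample(2:6, 1)
    genes <- paste0("g", 1:12)
    b <- make_bics(
      genes = lapply(seq_len(n_b), function(i) sort(sample(genes, sample(2:6, 1)))),
      conditions = lapply(seq_len(n_b), function(i) sort(sample(paste0("c", 1:8), sample(2:4, 1))))
    )
    nets <- build_network(b)
    nodes <- dplyr::bind_rows(lapply(nets, `[[`, "nodes"))
    edges <- dplyr::bind_rows(lapply(nets, `[[`, "edges"))
    orc <- oracle_network(b)

    # partition: node gene sets equal the oracle's, disjoint, covering
    expect_setequal(vapply(nodes$genes, paste, "", collapse = ","),
                    vapply(orc$nodes, paste, "", collapse = ","))
    all_genes <- unlist(nodes$genes)
    expect_false(any(duplicated(all_genes)))
    expect_setequal(all_genes, unique(unlist(b$genes)))

    # weight identity on every edge
    for (i in seq_len(nrow(edges))) {
      su <- nodes$signature[[match(edges$from[i], nodes$node_id)]]
      sv <- nodes$signature[[match(edges$to[i], nodes$node_id)]]
      expect_equal(edges$weight[i], length(intersect(su, sv)))
    }
    # clique property per bicluster
    for (bi in seq_len(n_b)) {
      members <- nodes$node_id[vapply(nodes$signature, function(s) bi %in% s, TRUE)]
      k <- length(members)
      if (k >= 2) {
        inside <- edges$from %in% members & edges$to %in% members
        pairs <- sum(inside)
        expect_gte(pairs, k * (k - 1) / 2)   # all pairs present (weight >= 1)
        cnt <- sum(vapply(which(inside), function(e) {
          su <- nodes$signature[[match(edges$from[e], nodes$node_id)]]
          sv <- nodes$signature[[match(edges$to[e], nodes$node_id)]]
          bi %in% intersect(su, sv)
        }, TRUE))
        expect_equal(cnt, k * (k - 1) / 2)
      }
    }
    # compactness
    expect_lte(nrow(nodes), length(unique(unlist(b$genes))))
  }
})

test_that("edge-weight filtering drops light edges and isolated nodes", {
  b <- fig_config_biclusters()
  net <- build_network(b)[[1]]
  same <- filter_by_edge_weight(net, 1)
  expect_length(same, 1)
  expect_equal(nrow(same[[1]]$nodes), 5)

  heavy <- filter_by_edge_weight(net, 2)
  expect_length(heavy, 1)                       # one 3-node path component
  expect_equal(nrow(heavy[[1]]$nodes), 3)
  expect_equal(nrow(heavy[[1]]$edges), 2)
  sigs <- lapply(heavy[[1]]$nodes$signature, identity)
  expect_setequal(vapply(sigs, paste, "", collapse = ","), c("1,2", "1,2,3", "2,3"))

  expect_length(filter_by_edge_weight(net, 99), 0)
})

test_that("node statistics and hub extraction follow the definitions", {
  b <- fig_config_biclusters()
  net <- build_network(b)[[1]]
  st <- node_stats(net)
  top <- st[1, ]
  expect_identical(net$nodes$signature[[match(top$node_id, net$nodes$node_id)]], 1:3)
  expect_equal(top$degree, 4L)

  hub <- extract_hub_subnetwork(net, min_weight = 2)
  expect_identical(net$nodes$signature[[match(hub$hub, net$nodes$node_id)]], 1:3)
  nb_sigs <- lapply(hub$neighbors, function(id) net$nodes$signature[[match(id, net$nodes$node_id)]])
  expect_setequal(vapply(nb_sigs, paste, "", collapse = ","), c("1,2", "2,3"))
  expect_setequal(hub$genes,
                  sort(unique(unlist(net$nodes$genes[net$nodes$node_id %in% c(hub$hub, hub$neighbors)]))))

  solo <- build_network(make_bics(list(c("g1", "g2")), list(c("c1", "c2"))))[[1]]
  h <- extract_hub_subnetwork(solo, 2)
  expect_length(h$neighbors, 0)
  st1 <- node_stats(solo)
  expect_equal(st1$degree, 0L)
  expect_equal(st1$weighted_degree, 0L)

  # star: center degree equals weighted degree for unit weights
  star <- make_bics(
    genes = list(c("hub1", "a1"), c("hub1", "b1"), c("hub1", "d1")),
    conditions = rep(list(c("c1", "c2")), 3)
  )
  snet <- build_network(star)[[1]]
  sst <- node_stats(snet)
  expect_equal(max(sst$degree), max(sst$weighted_degree))
})

test_that("GraphML and flat-table export round out the network surface", {
  net <- build_network(fig_config_biclusters())[[1]]
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 7)
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, tf)
  expect_true(file.exists(tf))
  g2 <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::ecount(g2), 7)
  expect_setequal(igraph::E(g2)$weight, net$edges$weight)

  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network_tables(net, prefix)
  expect_true(all(file.exists(paths)))
  nodes_tab <- readr::read_tsv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(nodes_tab), 5)
})
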