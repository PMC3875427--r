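# Gene set networks: nodes are maximal gene sets sharing an identical
# bicluster-membership signature; edge weight counts shared biclusters.

#' Build gene set networks from overlapping biclusters
#'
#' Every gene occurring in at least one bicluster is assigned its
#' membership signature (the exact set of biclusters containing it); genes
#' with identical signatures form one node.  Two nodes are joined by an
#' edge weighted by the number of biclusters shared by their signatures,
#' so the nodes of one bicluster always form a clique.  Connected
#' components are returned as separate networks, largest first.
#'
#' @param biclusters bicluster tibble with >= 1 row; bicluster ids are the
#'   row numbers.
#' @return A list of `gene_set_network` objects (class
#'   `gene_set_network_list`).  Each network has `nodes` (tibble: node_id,
#'   signature list, genes list, conditions list, n_genes) and `edges`
#'   (tibble: from, to, weight).
#' @export
build_network <- function(biclusters) {
  stopifnot(nrow(biclusters) >= 1)
  n_bic <- nrow(biclusters)
  gene_sig <- list()
  for (b in seq_len(n_bic)) {
    for (g in biclusters$genes[[b]]) gene_sig[[g]] <- c(gene_sig[[g]], b)
  }
  sig_key <- vapply(gene_sig, set_key, "")
  uniq <- sort(unique(sig_key))    # node ids by sorted signature tuple
  nodes <- tibble::tibble(
    node_id = seq_along(uniq),
    signature = lapply(uniq, function(k) as.integer(strsplit(k, ",")[[1]])),
    genes = lapply(uniq, function(k) sort(names(gene_sig)[sig_key == k]))
  )
  nodes$conditions <- lapply(nodes$signature, function(s) {
    sort(unique(unlist(biclusters$conditions[s])))
  })
  nodes$n_genes <- lengths(nodes$genes)

  m <- nrow(nodes)
  ef <- integer(); et <- integer(); ew <- integer()
  if (m > 1) {
    for (a in seq_len(m - 1)) {
      for (b in seq(a + 1, m)) {
        w <- length(intersect(nodes$signature[[a]], nodes$signature[[b]]))
        if (w >= 1) { ef <- c(ef, a); et <- c(et, b); ew <- c(ew, w) }
      }
    }
  }
  edges <- tibble::tibble(from = ef, to = et, weight = ew)
  split_components(nodes, edges)
}

# Split a node/edge table into connected components, largest first.
split_components <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$from, to = edges$to),
    directed = FALSE,
    vertices = data.frame(name = nodes$node_id)
  )
  comp <- igraph::components(g)
  member <- comp$membership[as.character(nodes$node_id)]
  sizes <- table(member)
  # order components: node count desc, then smallest member node id
  first_node <- tapply(nodes$node_id, member, min)
  comp_order <- order(-as.integer(sizes), as.integer(first_node))
  nets <- lapply(names(sizes)[comp_order], function(cid) {
    nidx <- which(member == as.integer(cid))
    ids <- nodes$node_id[nidx]
    structure(
      list(
        nodes = nodes[nidx, ],
        edges = edges[edges$from %in% ids & edges$to %in% ids, ]
      ),
      class = "gene_set_network"
    )
  })
  structure(nets, class = "gene_set_network_list")
}

#' @export
print.gene_set_network <- function(x, ...) {
  cat(sprintf("<gene_set_network> %d nodes, %d edges, %d genes%s\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$n_genes),
              if (nrow(x$nodes) == 1) " [singleton]" else ""))
  invisible(x)
}

#' @export
print.gene_set_network_list <- function(x, ...) {
  cat(sprintf("<gene_set_network_list> %d connected network(s)\n", length(x)))
  for (n in x) print(n)
  invisible(x)
}

#' Filter a network by edge weight
#'
#' Drops edges lighter than `min_weight` and the nodes isolated by that,
#' then re-splits into connected components.
#'
#' @param net a `gene_set_network`.
#' @param min_weight minimum retained edge weight (>= 1).
#' @return a `gene_set_network_list` of the surviving components.
#' @export
filter_by_edge_weight <- function(net, min_weight) {
  stopifnot(inherits(net, "gene_set_network"), min_weight >= 1)
  edges <- net$edges[net$edges$weight >= min_weight, ]
  live <- sort(unique(c(edges$from, edges$to)))
  nodes <- net$nodes[net$nodes$node_id %in% live, ]
  if (nrow(nodes) == 0) {
    return(structure(list(), class = "gene_set_network_list"))
  }
  split_components(nodes, edges)
}

#' Per-node degree statistics
#'
#' @param net a `gene_set_network`.
#' @return tibble (node_id, degree, weighted_degree, n_genes), degree
#'   descending, ties by node_id.
#' @export
node_stats <- function(net) {
  stopifnot(inherits(net, "gene_set_network"))
  ids <- net$nodes$node_id
  deg <- vapply(ids, function(i) sum(net$edges$from == i | net$edges$to == i), 0L)
  wdeg <- vapply(ids, function(i) {
    sum(net$edges$weight[net$edges$from == i | net$edges$to == i])
  }, 0)
  out <- tibble::tibble(node_id = ids, degree = as.integer(deg),
                        weighted_degree = as.integer(wdeg),
                        n_genes = net$nodes$n_genes)
  out[order(-out$degree, out$node_id), ]
}

#' Extract the hub neighborhood of a network
#'
#' The hub is the maximum-degree node (ties broken by smallest node id,
#' i.e. lexicographically smallest signature); its neighborhood is every
#' node adjacent through an edge of weight >= `min_weight`.  The gene list
#' (hub plus neighbors) is intended for export to external enrichment
#' tools.
#'
#' @param net a `gene_set_network`.
#' @param min_weight minimum edge weight into the neighborhood.
#' @return list with `hub` (node_id), `neighbors` (node_ids), `genes`
#'   (sorted union of hub and neighbor genes).
#' @export
extract_hub_subnetwork <- function(net, min_weight = 2) {
  stopifnot(inherits(net, "gene_set_network"))
  st <- node_stats(net)
  hub <- st$node_id[1]
  heavy <- net$edges[net$edges$weight >= min_weight, ]
  nb <- sort(unique(c(heavy$to[heavy$from == hub], heavy$from[heavy$to == hub])))
  genes <- sort(unique(unlist(net$nodes$genes[net$nodes$node_id %in% c(hub, nb)])))
  list(hub = hub, neighbors = nb, genes = genes)
}

#' Convert a gene set network to igraph
#'
#' Node attributes: genes (comma-joined), n_genes, signature
#' (comma-joined bicluster ids), conditions (comma-joined); edge attribute:
#' weight.
#'
#' @param net a `gene_set_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_set_network"))
  vert <- data.frame(
    name = as.character(net$nodes$node_id),
    genes = vapply(net$nodes$genes, set_key, ""),
    n_genes = net$nodes$n_genes,
    signature = vapply(net$nodes$signature, set_key, ""),
    conditions = vapply(net$nodes$conditions, set_key, "")
  )
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net$edges$from),
                   to = as.character(net$edges$to),
                   weight = net$edges$weight),
    directed = FALSE, vertices = vert
  )
}

#' Write a gene set network as GraphML
#'
#' @param net a `gene_set_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write flat node/edge tables and per-node gene lists
#'
#' Writes `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` and one
#' `<prefix>_node<k>_genes.txt` per node (one gene per line, ready for
#' pasting into external GO enrichment tools).
#'
#' @param net a `gene_set_network`.
#' @param prefix path prefix for the output files.
#' @return character vector of written paths, invisibly.
#' @export
write_network_tables <- function(net, prefix) {
  nodes_flat <- tibble::tibble(
    node_id = net$nodes$node_id,
    n_genes = net$nodes$n_genes,
    signature = vapply(net$nodes$signature, set_key, ""),
    conditions = vapply(net$nodes$conditions, set_key, ""),
    genes = vapply(net$nodes$genes, set_key, "")
  )
  paths <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"))
  readr::write_tsv(nodes_flat, paths[1], progress = FALSE)
  readr::write_tsv(net$edges, paths[2], progress = FALSE)
  for (i in seq_len(nrow(net$nodes))) {
    p <- paste0(prefix, "_node", net$nodes$node_id[i], "_genes.txt")
    writeLines(net$nodes$genes[[i]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
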