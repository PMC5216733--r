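# Seven per-node topology indices on undirected simple graphs, computed from
# scratch under per-connected-component normalization (the NetworkAnalyzer
# convention): correlation networks from small cohorts fragment into many
# small components, and global normalization would zero out their structure.
# Graphs are unweighted; correlation magnitude is an edge attribute, never a
# path weight.

#' Build a simple undirected graph from an edge list
#'
#' @param edges A `correlation_network`, or a data.frame / two-column matrix of
#'   symbol pairs. Self-loops are an error; duplicate unordered pairs collapse
#'   to one edge.
#' @param nodes Optional extra (possibly isolated) node symbols.
#' @return A `topo_graph`: list with `nodes` (character) and `adj` (list of
#'   integer neighbor indices).
#' @export
graph_from_edges <- function(edges, nodes = NULL) {
  if (inherits(edges, "correlation_network")) {
    nodes <- unique(c(nodes, edges$node_attrs$symbol))
    edges <- edges$edges
  }
  if (is.matrix(edges)) {
    edges <- data.frame(symbol_a = edges[, 1], symbol_b = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  a <- as.character(edges$symbol_a)
  b <- as.character(edges$symbol_b)
  if (any(a == b)) stopf("self-loops are not allowed")
  nodes <- sort(unique(c(nodes, a, b)))
  n <- length(nodes)
  if (n == 0) stopf("empty graph")
  key <- pair_key(a, b)
  keep <- !duplicated(key)
  ai <- match(a[keep], nodes)
  bi <- match(b[keep], nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (e in seq_along(ai)) {
    adj[[ai[e]]] <- c(adj[[ai[e]]], bi[e])
    adj[[bi[e]]] <- c(adj[[bi[e]]], ai[e])
  }
  adj <- lapply(adj, sort)
  structure(list(nodes = nodes, adj = adj), class = "topo_graph")
}

#' Single-source shortest paths (BFS) with path counts
#'
#' Unweighted breadth-first search from `source`, returning hop distances and
#' the number of distinct shortest paths to every reachable node.
#'
#' @param graph A `topo_graph` (or anything [graph_from_edges()] accepts).
#' @param source Source node symbol.
#' @return A list with named vectors `dist` and `sigma` over reachable nodes
#'   (the source itself has `dist = 0`, `sigma = 1`), and `order`, the nodes in
#'   non-decreasing distance order.
#' @export
shortest_paths <- function(graph, source) {
  if (!inherits(graph, "topo_graph")) graph <- graph_from_edges(graph)
  s <- match(source, graph$nodes)
  if (is.na(s)) stopf("source not in graph")
  res <- bfs_counts(graph$adj, s)
  reach <- which(res$dist >= 0)
  list(
    dist = setNames(res$dist[reach], graph$nodes[reach]),
    sigma = setNames(res$sigma[reach], graph$nodes[reach]),
    order = graph$nodes[res$order]
  )
}

# BFS returning dist (-1 unreachable), sigma path counts, visit order and
# predecessor lists - the substrate for Brandes accumulation.
bfs_counts <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n)
  sigma <- rep(0, n)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1] <- s
  qh <- 1L; qt <- 1L
  order <- integer(0)
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    order <- c(order, v)
    for (w in adj[[v]]) {
      if (dist[w] < 0) {
        dist[w] <- dist[v] + 1L
        qt <- qt + 1L
        queue[qt] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order)
}

connected_components <- function(adj) {
  n <- length(adj)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    stack <- s
    comp[s] <- cid
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

#' Per-node topology indices
#'
#' Computes, for every node, the seven indices: degree; degree centrality
#' `degree / (n - 1)` with `n` the graph order; betweenness (Brandes
#' accumulation, normalized by `2 / ((n_c - 1)(n_c - 2))` with `n_c` the
#' node's component order, 0 when `n_c < 3`); closeness `(n_c - 1) / sum(d)`;
#' average shortest path length `sum(d) / (n_c - 1)`; clustering coefficient
#' `2 e_N / (k (k - 1))` (0 when `k < 2`); and radiality
#' `(D_c + 1 - aspl) / D_c` with `D_c` the component diameter. Path-based
#' indices are computed within the node's connected component. Singleton
#' nodes report closeness 0, `NA` average path length and radiality 1 by
#' convention (flagged in `radiality_convention`).
#'
#' @param graph A `topo_graph`, `correlation_network`, or edge data.frame.
#' @param nodes Optional isolated nodes to include.
#' @return A data.frame with one row per node: `node`, `degree`,
#'   `degree_centrality`, `betweenness`, `closeness`, `clustering_coeff`,
#'   `radiality`, `aspl`, `component`, `component_size`,
#'   `radiality_convention`.
#' @export
node_metrics <- function(graph, nodes = NULL) {
  if (!inherits(graph, "topo_graph")) graph <- graph_from_edges(graph, nodes)
  adj <- graph$adj
  n <- length(adj)
  deg <- lengths(adj)
  comp <- connected_components(adj)
  csize <- tabulate(comp)[comp]

  # Brandes betweenness (unnormalized, undirected: halved at the end)
  btw <- rep(0, n)
  sum_dist <- rep(0, n)
  ecc <- rep(0L, n)
  for (s in seq_len(n)) {
    if (deg[s] == 0) next
    b <- bfs_counts(adj, s)
    reach <- b$dist >= 0
    sum_dist[s] <- sum(b$dist[reach])
    ecc[s] <- max(b$dist[reach])
    delta <- rep(0, n)
    for (w in rev(b$order)) {
      for (v in b$preds[[w]]) {
        delta[v] <- delta[v] + b$sigma[v] / b$sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  btw <- btw / 2

  btw_norm <- ifelse(csize >= 3, btw * 2 / ((csize - 1) * (csize - 2)), 0)
  closeness <- ifelse(csize >= 2, (csize - 1) / sum_dist, 0)
  aspl <- ifelse(csize >= 2, sum_dist / (csize - 1), NA_real_)

  # component diameter = max eccentricity within the component
  diam <- vapply(seq_len(n), function(i) {
    max(ecc[comp == comp[i]])
  }, 0L)
  radiality <- ifelse(diam >= 1, (diam + 1 - aspl) / diam, 1)
  convention <- diam < 1

  clust <- vapply(seq_len(n), function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- adj[[i]]
    e_n <- 0L
    for (j in seq_len(k - 1)) {
      e_n <- e_n + sum(adj[[nb[j]]] %in% nb[(j + 1):k])
    }
    2 * e_n / (k * (k - 1))
  }, 0)

  data.frame(
    node = graph$nodes,
    degree = as.integer(deg),
    degree_centrality = if (n > 1) deg / (n - 1) else 0,
    betweenness = btw_norm,
    closeness = closeness,
    clustering_coeff = clust,
    radiality = radiality,
    aspl = aspl,
    component = comp,
    component_size = as.integer(csize),
    radiality_convention = convention,
    stringsAsFactors = FALSE
  )
}

write_topology_tsv <- function(topo, path) {
  write.table(topo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
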