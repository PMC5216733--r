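# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: shortest paths by exhaustive simple-path
# enumeration (tiny graphs) or by pair-dependency counting over an
# independently computed distance matrix (larger graphs), BH by a literal
# step-up transcription, and detection rates by direct simulation.

# ---- graph representations -------------------------------------------------

# adjacency matrix from an edge matrix (rows = pairs of 1-based node indices)
adj_matrix <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (length(edges) > 0) {
    A[edges] <- 1L
    A[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  diag(A) <- 0L
  A
}

edges_to_df <- function(edges, nodes) {
  data.frame(symbol_a = nodes[edges[, 1]], symbol_b = nodes[edges[, 2]],
             stringsAsFactors = FALSE)
}

# ---- tiny-graph oracle: exhaustive simple-path enumeration -----------------

# All simple paths between s and t by depth-first enumeration; returns the
# shortest length and ALL shortest paths (as lists of intermediate nodes).
enumerate_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  recurse <- function(v, visited, path) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1L)) {
      if (!visited[w]) {
        visited[w] <- TRUE
        recurse(w, visited, c(path, w))
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  recurse(s, visited, s)
  if (length(paths) == 0) return(list(dist = Inf, paths = list()))
  lens <- vapply(paths, length, 0L) - 1L
  d <- min(lens)
  list(dist = d, paths = paths[lens == d])
}

# Full seven-metric oracle for tiny graphs by path enumeration.
oracle_metrics_enum <- function(A, nodes) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  inner <- matrix(0, n, n)  # pair (s,t) -> count of (path, interior node v) hits per v
  btw_raw <- rep(0, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    res <- enumerate_shortest_paths(A, s, t)
    D[s, t] <- D[t, s] <- res$dist
    sigma[s, t] <- sigma[t, s] <- length(res$paths)
    if (is.finite(res$dist) && res$dist >= 2) {
      for (p in res$paths) {
        interior <- p[-c(1, length(p))]
        btw_raw[interior] <- btw_raw[interior] + 1 / length(res$paths)
      }
    }
  }
  finish_oracle(A, D, sigma, btw_raw, nodes)
}

# ---- larger-graph oracle: distances by matrix powers + pair dependencies --

oracle_metrics_pairdep <- function(A, nodes) {
  n <- nrow(A)
  # distance matrix from powers of the adjacency matrix
  D <- matrix(Inf, n, n); diag(D) <- 0
  reach <- diag(n)
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- (P %*% A > 0) * 1
    newly <- P > 0 & !is.finite(D)
    if (!any(newly)) break
    D[newly] <- k
  }
  # shortest-path counts by DP over increasing distance
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    ds <- D[s, ]
    for (d in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (w in which(ds == d)) {
        pred <- which(A[, w] == 1L & ds == d - 1)
        sigma[s, w] <- sum(sigma[s, pred])
      }
    }
  }
  btw_raw <- rep(0, n)
  for (v in seq_len(n)) {
    on_path <- is.finite(D) & outer(D[, v], D[v, ], "+") == D
    on_path[v, ] <- FALSE
    on_path[, v] <- FALSE
    diag(on_path) <- FALSE
    W <- outer(sigma[, v], sigma[v, ]) / sigma
    W[!on_path] <- 0
    btw_raw[v] <- sum(W[upper.tri(W)])
  }
  finish_oracle(A, D, sigma, btw_raw, nodes)
}

# shared final assembly: normalizations from the distance/adjacency matrices
finish_oracle <- function(A, D, sigma, btw_raw, nodes) {
  n <- nrow(A)
  comp_of <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp_of[i])) next
    cid <- cid + 1
    comp_of[is.finite(D[i, ])] <- cid
  }
  out <- data.frame(node = nodes, degree = rowSums(A),
                    stringsAsFactors = FALSE)
  out$degree_centrality <- if (n > 1) out$degree / (n - 1) else 0
  out$betweenness <- out$closeness <- out$clustering_coeff <- 0
  out$radiality <- 1
  out$aspl <- NA_real_
  for (i in seq_len(n)) {
    members <- which(comp_of == comp_of[i])
    nc <- length(members)
    if (nc >= 3) {
      out$betweenness[i] <- btw_raw[i] * 2 / ((nc - 1) * (nc - 2))
    }
    if (nc >= 2) {
      sd_ <- sum(D[i, members])
      out$closeness[i] <- (nc - 1) / sd_
      out$aspl[i] <- sd_ / (nc - 1)
      diam <- max(D[members, members])
      out$radiality[i] <- (diam + 1 - out$aspl[i]) / diam
    }
    k <- out$degree[i]
    if (k >= 2) {
      nb <- which(A[i, ] == 1L)
      out$clustering_coeff[i] <- sum(A[nb, nb]) / (k * (k - 1))
    }
  }
  out
}

# max absolute deviation across the seven indices (Inf on NA-pattern mismatch)
compare_topology <- function(got, want) {
  stopifnot(identical(got$node, want$node))
  if (!identical(is.na(got$aspl), is.na(want$aspl))) return(Inf)
  cols <- c("degree", "degree_centrality", "betweenness", "closeness",
            "clustering_coeff", "radiality")
  devs <- vapply(cols, function(cl) max(abs(got[[cl]] - want[[cl]])), 0)
  aspl <- abs(got$aspl - want$aspl)
  max(c(devs, aspl[!is.na(aspl)], 0))
}

# ---- random graphs ---------------------------------------------------------

random_er_edges <- function(n, p) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[runif(nrow(idx)) < p, , drop = FALSE]
}

random_connected_edges <- function(n, extra = n) {
  # random spanning tree plus extra random edges
  perm <- sample(n)
  tree <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 0L)])
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  more <- idx[sample(nrow(idx), min(extra, nrow(idx))), , drop = FALSE]
  e <- rbind(tree, more)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# ---- other oracles ---------------------------------------------------------

# Literal BH step-up transcription, independent of stats::p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Brute-force partition of two signed edge sets (keyed pairs).
partition_bruteforce <- function(t_keys, t_signs, c_keys, c_signs) {
  all_keys <- union(t_keys, c_keys)
  out <- list(common = character(), sign_flip = character(),
              tumor_exclusive = character(), control_exclusive = character())
  for (k in all_keys) {
    it <- match(k, t_keys); ic <- match(k, c_keys)
    if (!is.na(it) && !is.na(ic)) {
      if (t_signs[it] == c_signs[ic]) {
        out$common <- c(out$common, k)
      } else {
        out$sign_flip <- c(out$sign_flip, k)
      }
    } else if (!is.na(it)) {
      out$tumor_exclusive <- c(out$tumor_exclusive, k)
    } else {
      out$control_exclusive <- c(out$control_exclusive, k)
    }
  }
  lapply(out, sort)
}

# Monte-Carlo detection probability of the edge rule (|r| >= r_cut, p <= alpha)
# for a bivariate normal pair at correlation rho with n observations.
simulate_edge_detection <- function(rho, n, r_cut, alpha, reps) {
  hits <- 0
  for (i in seq_len(reps)) {
    f <- rnorm(n)
    x <- sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * rnorm(n)
    y <- sign(rho) * sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * rnorm(n)
    r <- cor(x, y)
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t), n - 2)
    if (abs(r) >= r_cut && p <= alpha) hits <- hits + 1
  }
  hits / reps
}

make_set <- function(control, tumor, symbols = NULL, patients = NULL) {
  symbols <- symbols %||% rownames(control) %||%
    sprintf("f%02d", seq_len(nrow(control)))
  patients <- patients %||% sprintf("P%02d", seq_len(ncol(control)))
  paired_expression_set(symbols, patients, control, tumor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
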