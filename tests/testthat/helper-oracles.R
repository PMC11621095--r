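# Independent brute-force oracles, deliberately written without igraph or any
# package graph routine, so metric implementations are checked against a
# second route.

# binary_net from a plain adjacency matrix
make_net <- function(adj, sparsity = NA_real_) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "integer"
  labels <- sprintf("N%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, sparsity = sparsity,
                 edge_count = as.integer(sum(adj) / 2),
                 region_labels = labels),
            class = "binary_net")
}

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  a
}

rand_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

ring_lattice_adj <- function(n, k) {
  # each node linked to its k/2 nearest neighbours on each side
  a <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      a[i, j] <- 1L; a[j, i] <- 1L
    }
  }
  a
}

# Floyd-Warshall all-pairs shortest paths
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# clustering by explicit triangle enumeration
brute_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (adj[nb[a], nb[b]] == 1) t_i <- t_i + 1
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  list(nodal = ci, Cp = mean(ci))
}

brute_nodal_efficiency <- function(adj) {
  d <- fw_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

brute_global_efficiency <- function(adj) mean(brute_nodal_efficiency(adj))

brute_local_efficiency <- function(adj) {
  n <- nrow(adj)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    le[i] <- brute_global_efficiency(adj[nb, nb, drop = FALSE])
  }
  list(nodal = le, Eloc = mean(le))
}

# all shortest paths between s and t by recursive enumeration over the BFS
# distance field
enumerate_shortest_paths <- function(adj, dist_s, s, t) {
  if (!is.finite(dist_s[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] == 1 & dist_s == dist_s[v] - 1)
    out <- list()
    for (u in preds)
      for (pth in walk(u)) out[[length(out) + 1]] <- c(pth, v)
    out
  }
  walk(t)
}

# unnormalized betweenness by exhaustive shortest-path counting
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_shortest_paths(adj, d[s, ], s, t)
      if (length(paths) == 0) next
      for (pth in paths) {
        inner <- setdiff(pth, c(s, t))
        b[inner] <- b[inner] + 1 / length(paths)
      }
    }
  }
  b
}

# component edge sizes via union-find
uf_component_edge_sizes <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  if (nrow(ut) == 0) return(integer(0))
  for (r in seq_len(nrow(ut))) {
    a <- find(ut[r, 1]); b <- find(ut[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(ut[, 1], find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# small helper cohort for connectome-level tests
toy_roi_ts <- function(values, tr = 1) {
  roi_timeseries(values, sprintf("R%02d", seq_len(ncol(values))), tr)
}
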