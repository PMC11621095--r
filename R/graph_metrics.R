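# Global and nodal graph metrics on binary networks, degree-preserving null
# normalization, and AUC summaries over the sparsity grid. Graph primitives
# (BFS distances, transitivity, betweenness, rewiring) come from igraph; the
# conventions fixed here are: clustering and local efficiency are averaged
# over all N nodes (isolated nodes contribute 0), and the characteristic path
# length on a fragmented graph is the mean over connected pairs (with a
# warning carrying the component count).

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficient
#'
#' Per node, `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of
#' triangles through node i; `C_i = 0` when the degree `k_i < 2`. `Cp` is the
#' mean over all N nodes.
#'
#' @param net a `binary_net`.
#' @return list with `nodal` (per-node C_i) and `Cp`.
#' @export
clustering_coefficient <- function(net) {
  ci <- igraph::transitivity(as_igraph(net), type = "local",
                             isolates = "zero")
  list(nodal = as.numeric(ci), Cp = mean(ci))
}

#' Pairwise shortest-path (hop) distances
#'
#' @param net a `binary_net`.
#' @return N x N matrix of breadth-first hop distances; unreachable pairs are
#'   `Inf`.
#' @export
shortest_path_lengths <- function(net) {
  igraph::distances(as_igraph(net), algorithm = "unweighted")
}

#' Characteristic path length
#'
#' Mean hop distance over connected ordered pairs. On a fragmented graph the
#' unreachable pairs are excluded and a warning reports the component count.
#'
#' @param net a `binary_net`.
#' @param warn_fragmented emit the fragmentation warning (default TRUE).
#' @return Lp (scalar).
#' @export
characteristic_path_length <- function(net, warn_fragmented = TRUE) {
  if (net$edge_count < 1) stop("graph has no edges; Lp undefined")
  d <- shortest_path_lengths(net)
  off <- d[row(d) != col(d)]
  if (any(is.infinite(off)) && warn_fragmented) {
    nc <- igraph::count_components(as_igraph(net))
    warning("graph is fragmented (", nc,
            " components); Lp averaged over connected pairs")
  }
  mean(off[is.finite(off)])
}

#' Global and nodal efficiency
#'
#' `e_i = (1/(N-1)) * sum_{j != i} 1/d_ij` with `1/Inf = 0`;
#' `Eglob = mean(e_i)`.
#'
#' @param net a `binary_net`.
#' @return `nodal_efficiency` returns the per-node vector; `global_efficiency`
#'   returns the scalar mean.
#' @export
nodal_efficiency <- function(net) {
  d <- shortest_path_lengths(net)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  as.numeric(rowSums(inv) / (nrow(inv) - 1))
}

#' @rdname nodal_efficiency
#' @export
global_efficiency <- function(net) mean(nodal_efficiency(net))

# hop distances on a small dense adjacency block by repeated boolean
# matrix products (subgraphs here are <= N nodes with tiny diameters)
dense_hop_distances <- function(A) {
  k <- nrow(A)
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  D[A > 0] <- 1
  reach <- A > 0
  step <- 1
  while (any(is.infinite(D[row(D) != col(D)])) && step < k) {
    reach <- (reach %*% A) > 0
    step <- step + 1
    D[reach & is.infinite(D)] <- step
  }
  D
}

#' Local efficiency
#'
#' Per node: the global efficiency of the subgraph induced by the node's
#' neighbours (0 when the degree is below 2), i.e. paths between neighbours
#' may only pass through other neighbours; `Eloc` is the mean over all N
#' nodes.
#'
#' @param net a `binary_net`.
#' @return list with `nodal` and `Eloc`.
#' @export
local_efficiency <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    D <- dense_hop_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / D
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    le[i] <- sum(inv) / (k * (k - 1))
  }
  list(nodal = le, Eloc = mean(le))
}

#' Nodal degree and betweenness
#'
#' Betweenness is the unnormalized shortest-path betweenness (sum over node
#' pairs of the fraction of shortest paths passing through the node,
#' endpoints excluded).
#'
#' @param net a `binary_net`.
#' @return numeric vector, one value per node.
#' @export
node_degree <- function(net) as.numeric(rowSums(net$adjacency))

#' @rdname node_degree
#' @export
betweenness_centrality <- function(net) {
  as.numeric(igraph::betweenness(as_igraph(net), directed = FALSE,
                                 normalized = FALSE))
}

#' Degree-preserving random-network ensemble
#'
#' Each null network is produced by seeded double-edge swaps (Maslov-Sneppen
#' rewiring) that reject self-loops and duplicate edges, so the degree
#' sequence is preserved exactly. Returns the mean clustering coefficient and
#' characteristic path length over the ensemble, used for small-world
#' normalization.
#'
#' @param net a `binary_net` with at least 2 edges.
#' @param n_nulls ensemble size (default 1000).
#' @param swap_factor attempted swaps = `swap_factor * edge_count`.
#' @param seed integer seed; the ensemble is deterministic given it.
#' @param keep_graphs also return the null `binary_net`s (for testing).
#' @return list with `n_nulls`, `swap_factor`, `seed`, `Cp_rand_mean`,
#'   `Lp_rand_mean`, per-null vectors `Cp_rand`, `Lp_rand`, and optionally
#'   `graphs`.
#' @export
degree_preserving_nulls <- function(net, n_nulls = 1000L, swap_factor = 10L,
                                    seed = 1L, keep_graphs = FALSE) {
  if (net$edge_count < 2) stop("need at least 2 edges to rewire")
  g <- as_igraph(net)
  n <- nrow(net$adjacency)
  if (net$edge_count == n * (n - 1) / 2)
    warning("complete graph admits no degree-preserving swap; ",
            "nulls are copies of the input")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cp <- lp <- numeric(n_nulls)
  graphs <- if (keep_graphs) vector("list", n_nulls) else NULL
  niter <- max(1L, as.integer(swap_factor) * net$edge_count)
  for (b in seq_len(n_nulls)) {
    gb <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    cp[b] <- mean(igraph::transitivity(gb, type = "local",
                                       isolates = "zero"))
    lp[b] <- igraph::mean_distance(gb, unconnected = TRUE)
    if (keep_graphs) graphs[[b]] <- gb
  }
  out <- list(n_nulls = as.integer(n_nulls),
              swap_factor = as.integer(swap_factor), seed = as.integer(seed),
              Cp_rand_mean = mean(cp), Lp_rand_mean = mean(lp),
              Cp_rand = cp, Lp_rand = lp)
  if (keep_graphs) out$graphs <- graphs
  out
}

#' Small-world indices
#'
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand`, `sigma = gamma / lambda`;
#' a small-world network satisfies `gamma > 1`, `lambda ~ 1`, `sigma > 1`.
#'
#' @param net a `binary_net`.
#' @param nulls a [degree_preserving_nulls()] ensemble computed on `net`.
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(net, nulls) {
  if (nulls$Cp_rand_mean == 0)
    stop("null ensemble has zero mean clustering; gamma undefined")
  cp <- clustering_coefficient(net)$Cp
  lp <- characteristic_path_length(net, warn_fragmented = FALSE)
  gamma <- cp / nulls$Cp_rand_mean
  lambda <- lp / nulls$Lp_rand_mean
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global metrics of one binary network
#'
#' @param net a `binary_net`.
#' @param nulls optional null ensemble; when supplied, gamma/lambda/sigma are
#'   included.
#' @return one-row data.frame with Cp, Lp, Eglob, Eloc (and gamma, lambda,
#'   sigma when `nulls` is given).
#' @export
global_metrics <- function(net, nulls = NULL) {
  out <- data.frame(Cp = clustering_coefficient(net)$Cp,
                    Lp = characteristic_path_length(net,
                                                    warn_fragmented = FALSE),
                    Eglob = global_efficiency(net),
                    Eloc = local_efficiency(net)$Eloc)
  if (!is.null(nulls)) {
    sw <- small_world(net, nulls)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
  }
  out
}

#' Nodal metrics of one binary network
#'
#' @param net a `binary_net`.
#' @return data.frame: node label, degree, efficiency, betweenness,
#'   local_efficiency.
#' @export
nodal_metrics <- function(net) {
  data.frame(node = net$region_labels,
             degree = node_degree(net),
             efficiency = nodal_efficiency(net),
             betweenness = betweenness_centrality(net),
             local_efficiency = local_efficiency(net)$nodal,
             stringsAsFactors = FALSE)
}

#' Trapezoidal area under a metric curve over the sparsity grid
#'
#' @param values numeric vector, one finite metric value per grid point.
#' @param grid sparsity values (strictly increasing).
#' @return the trapezoidal integral (metric units x sparsity).
#' @export
metric_auc <- function(values, grid) {
  if (length(values) != length(grid))
    stop("need one metric value per grid point (", length(grid), "); got ",
         length(values))
  if (any(!is.finite(values))) stop("non-finite metric value in AUC input")
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with >= 2 points")
  sum(diff(grid) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Long-format metric table for a set of subjects
#'
#' Computes global (and optionally nodal) metrics for every subject at every
#' sparsity of the grid. Small-world indices are included when `n_nulls > 0`
#' (null ensembles are generated per subject per sparsity with seeds derived
#' from `seed`).
#'
#' @param connectomes named list of `connectome` objects (names = subject
#'   ids).
#' @param grid sparsity grid.
#' @param nodal compute nodal metrics as well (degree, efficiency,
#'   betweenness, local efficiency).
#' @param n_nulls nulls per network for gamma/lambda/sigma (0 to skip).
#' @param swap_factor,seed null-ensemble settings.
#' @param rank edge ranking rule passed to [sweep_sparsity()].
#' @return data.frame: subject_id, sparsity, metric, node ("global" for
#'   global metrics), value.
#' @export
metric_table <- function(connectomes, grid = sparsity_grid(), nodal = TRUE,
                         n_nulls = 0L, swap_factor = 10L, seed = 1L,
                         rank = "signed") {
  stopifnot(length(names(connectomes)) == length(connectomes))
  rows <- vector("list", 0)
  for (sid in names(connectomes)) {
    nets <- sweep_sparsity(connectomes[[sid]], grid, rank)
    for (k in seq_along(grid)) {
      net <- nets[[k]]
      nulls <- if (n_nulls > 0)
        degree_preserving_nulls(net, n_nulls, swap_factor,
                                seed = derive_seed(seed, k * 1000 +
                                                     match(sid, names(connectomes))))
      else NULL
      gm <- global_metrics(net, nulls)
      rows[[length(rows) + 1]] <-
        data.frame(subject_id = sid, sparsity = grid[k],
                   metric = names(gm), node = "global",
                   value = as.numeric(gm[1, ]), stringsAsFactors = FALSE)
      if (nodal) {
        nm <- nodal_metrics(net)
        long <- do.call(rbind, lapply(
          c("degree", "efficiency", "betweenness", "local_efficiency"),
          function(m) data.frame(subject_id = sid, sparsity = grid[k],
                                 metric = m, node = nm$node,
                                 value = nm[[m]], stringsAsFactors = FALSE)))
        rows[[length(rows) + 1]] <- long
      }
    }
  }
  do.call(rbind, rows)
}

#' AUC table from a metric table
#'
#' One AUC per subject x metric x node, integrated over the grid; errors if a
#' subject/metric combination is missing any grid point.
#'
#' @param mt a [metric_table()].
#' @param grid the sparsity grid the table was computed on.
#' @return data.frame: subject_id, metric, node, auc.
#' @export
auc_table <- function(mt, grid = sparsity_grid()) {
  key <- interaction(mt$subject_id, mt$metric, mt$node, drop = TRUE)
  parts <- split(mt, key)
  out <- lapply(parts, function(d) {
    d <- d[order(d$sparsity), ]
    if (nrow(d) != length(grid) || any(abs(d$sparsity - grid) > 1e-12))
      stop("missing grid point(s) for ", d$subject_id[1], " / ",
           d$metric[1], " / ", d$node[1])
    data.frame(subject_id = d$subject_id[1], metric = d$metric[1],
               node = d$node[1], auc = metric_auc(d$value, grid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
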