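# Weighted (Fisher-z) and binary functional networks.

#' Pearson correlation matrix of regional time series
#'
#' @param ts an `roi_ts` with at least 3 volumes.
#' @return regions x regions symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  if (n_volumes(ts) < 3) stop("need at least 3 volumes")
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(ts$region_labels[sds == 0], collapse = ", "))
  r <- stats::cor(ts$values)
  (r + t(r)) / 2
}

#' Fisher r-to-z transformed connectome
#'
#' Applies `z = atanh(r)` to the off-diagonal entries and sets the diagonal to
#' zero. Off-diagonal `|r| >= 1` is clipped to `1 - 1e-7` with a warning.
#'
#' @param r_matrix symmetric correlation matrix.
#' @param region_labels optional labels (defaults to matrix dimnames).
#' @return an object of class `connectome`: list with `z_matrix` and
#'   `region_labels`.
#' @export
fisher_z <- function(r_matrix, region_labels = NULL) {
  r <- as.matrix(r_matrix)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-12)
    stop("correlation matrix must be symmetric")
  if (is.null(region_labels))
    region_labels <- colnames(r) %||% sprintf("R%03d", seq_len(ncol(r)))
  off <- row(r) != col(r)
  n_clip <- sum(abs(r[off]) >= 1)
  if (n_clip > 0) {
    warning("clipped ", n_clip, " off-diagonal correlation(s) with |r| >= 1")
    r[off] <- pmin(pmax(r[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- list(region_labels, region_labels)
  structure(list(z_matrix = z, region_labels = as.character(region_labels)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$z_matrix), " x ", ncol(x$z_matrix),
      " Fisher-z matrix\n", sep = "")
  invisible(x)
}

#' Build a connectome from an ROI time series
#'
#' Convenience wrapper: [correlation_matrix()] then [fisher_z()].
#'
#' @param ts an `roi_ts`.
#' @return a `connectome`.
#' @export
build_connectome <- function(ts) {
  fisher_z(correlation_matrix(ts), ts$region_labels)
}

#' Sparsity grid for the threshold sweep
#'
#' Default 0.032 to 0.492 in steps of 0.01 (47 values). Values are generated
#' from integer indices to avoid floating-point drift.
#'
#' @param s_min,s_max,step sparsity bounds and increment.
#' @return numeric vector of sparsity values.
#' @export
sparsity_grid <- function(s_min = 0.032, s_max = 0.492, step = 0.01) {
  lo <- round(s_min * 1000)
  hi <- round(s_max * 1000)
  by <- round(step * 1000)
  if (by <= 0 || lo <= 0 || hi >= 1000 || lo > hi)
    stop("invalid sparsity grid")
  seq(lo, hi, by = by) / 1000
}

# descending rank of upper-triangle edges; ties broken by (i, j) index order
edge_ranking <- function(conn, rank = c("signed", "abs")) {
  rank <- match.arg(rank)
  z <- conn$z_matrix
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[upper.tri(z)]
  if (rank == "abs") w <- abs(w)
  ord <- order(-w, ut[, 1], ut[, 2])
  list(i = ut[ord, 1], j = ut[ord, 2], n = n)
}

make_binary_net <- function(ranking, k, s, labels) {
  n <- ranking$n
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  ii <- ranking$i[seq_len(k)]
  jj <- ranking$j[seq_len(k)]
  adj[cbind(ii, jj)] <- 1L
  adj[cbind(jj, ii)] <- 1L
  structure(list(adjacency = adj, sparsity = s, edge_count = as.integer(k),
                 region_labels = labels),
            class = "binary_net")
}

#' @export
print.binary_net <- function(x, ...) {
  cat("<binary_net> ", nrow(x$adjacency), " nodes, ", x$edge_count,
      " edges (sparsity ", format(x$sparsity), ")\n", sep = "")
  invisible(x)
}

#' Binarize a connectome at a target sparsity
#'
#' Keeps exactly `k = round(s * N(N-1)/2)` strongest off-diagonal edges
#' (rounding half away from zero). By default edges are ranked by signed
#' Fisher-z value, i.e. the most positive correlations are kept;
#' `rank = "abs"` ranks by magnitude instead. Ties are broken by lexicographic
#' node-index order.
#'
#' @param conn a `connectome`.
#' @param s target sparsity in (0, 1).
#' @param rank `"signed"` (default) or `"abs"`.
#' @return a `binary_net` with fields `adjacency`, `sparsity`, `edge_count`.
#' @export
binarize_at_sparsity <- function(conn, s, rank = c("signed", "abs")) {
  if (s <= 0 || s >= 1) stop("sparsity must be in (0, 1)")
  ranking <- edge_ranking(conn, rank)
  n_pairs <- ranking$n * (ranking$n - 1) / 2
  k <- round_half_away(s * n_pairs)
  if (k < 1) stop("sparsity ", s, " yields zero edges for N = ", ranking$n)
  make_binary_net(ranking, k, s, conn$region_labels)
}

#' Sweep a connectome across the sparsity grid
#'
#' One [binarize_at_sparsity()] result per grid value, computed from a single
#' fixed edge ranking, so the networks are nested (the edge set at a lower
#' sparsity is a subset of the edge set at any higher sparsity).
#'
#' @param conn a `connectome`.
#' @param grid numeric vector from [sparsity_grid()].
#' @inheritParams binarize_at_sparsity
#' @return list of `binary_net`, named by sparsity value.
#' @export
sweep_sparsity <- function(conn, grid = sparsity_grid(),
                           rank = c("signed", "abs")) {
  ranking <- edge_ranking(conn, rank)
  n_pairs <- ranking$n * (ranking$n - 1) / 2
  out <- lapply(grid, function(s) {
    k <- round_half_away(s * n_pairs)
    if (k < 1) stop("sparsity ", s, " yields zero edges")
    make_binary_net(ranking, k, s, conn$region_labels)
  })
  names(out) <- format(grid)
  out
}

#' Write a binary network as an edge list TSV
#'
#' Columns: region index i, region index j, weight 1.
#'
#' @param net a `binary_net`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  ut <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  utils::write.table(data.frame(i = ut[, 1], j = ut[, 2], w = 1L),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write BrainNet-Viewer-compatible .node and .edge files
#'
#' `.edge` is the N x N adjacency as an ASCII matrix; `.node` carries
#' placeholder coordinates (0 0 0), a color column (1), node degree as size,
#' and the region label.
#'
#' @param net a `binary_net`.
#' @param node_path,edge_path output files.
#' @param coords optional N x 3 matrix of node coordinates.
#' @export
write_brainnet <- function(net, node_path, edge_path, coords = NULL) {
  n <- nrow(net$adjacency)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  deg <- rowSums(net$adjacency)
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     color = 1L, size = deg, label = net$region_labels)
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_matrix_tsv(net$adjacency, edge_path)
  invisible(c(node_path, edge_path))
}
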