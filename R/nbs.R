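# Network-based statistic: edge-wise covariate-adjusted t maps,
# supra-threshold component extraction, and max-component-size permutation
# inference with family-wise error control.

# stack subjects' upper-triangle Fisher-z values into an n_subjects x n_edges
# matrix; column order matches which(upper.tri) of the z matrix
edge_value_matrix <- function(z_list) {
  n <- nrow(z_list[[1]]$z_matrix)
  ut <- upper.tri(z_list[[1]]$z_matrix)
  Y <- t(vapply(z_list, function(cc) {
    if (nrow(cc$z_matrix) != n) stop("connectome dimension mismatch")
    cc$z_matrix[ut]
  }, numeric(sum(ut))))
  attr(Y, "n_regions") <- n
  Y
}

# vectorized OLS group t for every edge: one QR of the design, applied to all
# edge outcomes at once
edge_group_t <- function(Y, X) {
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  qx <- qr(X)
  xtx_inv <- chol2inv(qr.R(qx))
  piv <- qx$pivot
  vg <- diag(xtx_inv)[order(piv)][which(colnames(X) == "group")]
  beta <- qr.coef(qx, Y)               # p x n_edges, original column order
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * vg)
  tval <- beta[which(colnames(X) == "group"), ] / se
  tval[se == 0] <- 0
  list(t = as.numeric(tval), df = df)
}

#' Edge-wise group t map
#'
#' Per off-diagonal edge, the group-coefficient t statistic from the same
#' covariate-adjusted GLM used for the AUC metrics, applied to the subjects'
#' Fisher-z values of that edge. Edges exceeding the primary threshold in the
#' requested tail form the supra-threshold adjacency.
#'
#' @param z_list list of `connectome` objects, one per subject, in design row
#'   order.
#' @param design a [design_matrix()].
#' @param tail `"patient_gt"` (patients > controls) or `"patient_lt"`.
#' @param primary_p primary edge-level p threshold (two-tailed within the
#'   signed tail; default 0.01). Alternatively give `primary_t` directly.
#' @param primary_t optional explicit t threshold (overrides `primary_p`).
#' @return list of class `edge_stat_map`: `t_matrix` (symmetric, zero
#'   diagonal), `primary_threshold` (t units), `supra_adjacency`, `df`,
#'   `tail`.
#' @export
edge_t_map <- function(z_list, design, tail = c("patient_gt", "patient_lt"),
                       primary_p = 0.01, primary_t = NULL) {
  tail <- match.arg(tail)
  if (length(z_list) != nrow(design))
    stop("number of connectomes (", length(z_list),
         ") does not match design rows (", nrow(design), ")")
  Y <- edge_value_matrix(z_list)
  res <- edge_group_t(Y, unclass(design))
  n <- attr(Y, "n_regions")
  labels <- z_list[[1]]$region_labels
  tm <- matrix(0, n, n, dimnames = list(labels, labels))
  tm[upper.tri(tm)] <- res$t
  tm <- tm + t(tm)
  t_crit <- primary_t %||% stats::qt(1 - primary_p / 2, res$df)
  supra <- if (tail == "patient_gt") (tm > t_crit) else (tm < -t_crit)
  supra <- supra & upper.tri(tm) | t(supra & upper.tri(tm))
  structure(list(t_matrix = tm, primary_threshold = t_crit,
                 supra_adjacency = supra * 1L, df = res$df, tail = tail),
            class = "edge_stat_map")
}

#' Connected components of a supra-threshold edge graph
#'
#' Components are taken over the graph whose edges are the supra-threshold
#' edges; component size is counted in edges, and isolated nodes are ignored.
#'
#' @param supra_adjacency binary symmetric matrix.
#' @return list of components, each a list with `nodes` (indices), `edges`
#'   (m x 2 matrix of node-index pairs) and `size_in_edges`; ordered by
#'   decreasing size.
#' @export
supra_components <- function(supra_adjacency) {
  A <- as.matrix(supra_adjacency)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (cid in seq_len(comp$no)) {
    nodes <- which(comp$membership == cid)
    if (length(nodes) < 2) next
    sub <- A[nodes, nodes, drop = FALSE]
    m <- sum(sub) / 2
    if (m < 1) next
    ut <- which(upper.tri(sub) & sub == 1, arr.ind = TRUE)
    out[[length(out) + 1]] <- list(nodes = nodes,
                                   edges = cbind(nodes[ut[, 1]],
                                                 nodes[ut[, 2]]),
                                   size_in_edges = as.integer(m))
  }
  out[order(-vapply(out, `[[`, integer(1), "size_in_edges"))]
}

max_component_size <- function(supra_adjacency) {
  comps <- supra_components(supra_adjacency)
  if (length(comps) == 0) 0L else comps[[1]]$size_in_edges
}

#' Network-based statistic permutation test
#'
#' Permutes group labels (covariates stay attached to their subjects),
#' recomputes the edge t map and the maximal supra-threshold component size
#' per permutation, and assigns each observed component the corrected p value
#' `(1 + #{null max sizes >= observed size}) / (1 + n_permutations)` -- never
#' exactly zero. Deterministic given `seed`.
#'
#' @inheritParams edge_t_map
#' @param n_permutations number of label permutations (>= 100; default 5000).
#' @param seed integer seed.
#' @param alpha family-wise significance level used for the `significant`
#'   flags.
#' @return object of class `nbs_result`: `components` (each with nodes,
#'   edges, size_in_edges, corrected_p, significant, edge t values),
#'   `null_max_sizes`, `primary_threshold`, `n_permutations`, `seed`, `tail`.
#' @export
nbs_permutation_test <- function(z_list, design,
                                 tail = c("patient_gt", "patient_lt"),
                                 primary_p = 0.01, primary_t = NULL,
                                 n_permutations = 5000L, seed = 1L,
                                 alpha = 0.05) {
  tail <- match.arg(tail)
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (1 / (1 + n_permutations) > alpha)
    warning("n_permutations too small to resolve alpha = ", alpha)
  obs <- edge_t_map(z_list, design, tail, primary_p, primary_t)
  comps <- supra_components(obs$supra_adjacency)
  Y <- edge_value_matrix(z_list)
  X <- unclass(design)
  n <- nrow(X)
  nr <- attr(Y, "n_regions")
  gidx <- which(colnames(X) == "group")
  t_crit <- obs$primary_threshold
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_max <- integer(n_permutations)
  ut_idx <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  for (b in seq_len(n_permutations)) {
    Xp <- X
    Xp[, gidx] <- X[sample(n), gidx]
    tv <- edge_group_t(Y, Xp)$t
    hit <- if (tail == "patient_gt") tv > t_crit else tv < -t_crit
    if (!any(hit)) { null_max[b] <- 0L; next }
    eg <- igraph::graph_from_edgelist(ut_idx[hit, , drop = FALSE],
                                      directed = FALSE)
    cs <- igraph::components(eg)
    # size in edges per component of the supra edge graph
    memb <- cs$membership[ut_idx[hit, 1]]
    null_max[b] <- max(tabulate(memb))
  }
  for (k in seq_along(comps)) {
    sz <- comps[[k]]$size_in_edges
    comps[[k]]$corrected_p <- (1 + sum(null_max >= sz)) / (1 + n_permutations)
    comps[[k]]$significant <- comps[[k]]$corrected_p < alpha
    comps[[k]]$t_values <- obs$t_matrix[comps[[k]]$edges]
  }
  structure(list(components = comps, null_max_sizes = null_max,
                 primary_threshold = t_crit, primary_p = primary_p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), tail = tail,
                 t_matrix = obs$t_matrix,
                 supra_adjacency = obs$supra_adjacency,
                 region_labels = z_list[[1]]$region_labels),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> tail =", x$tail, "| primary |t| >",
      round(x$primary_threshold, 3), "|", x$n_permutations,
      "permutations\n")
  if (length(x$components) == 0) {
    cat("  no supra-threshold components\n")
  } else for (k in seq_along(x$components)) {
    cc <- x$components[[k]]
    cat(sprintf("  component %d: %d nodes, %d edges, corrected p = %.4f%s\n",
                k, length(cc$nodes), cc$size_in_edges, cc$corrected_p,
                if (cc$significant) " *" else ""))
  }
  invisible(x)
}

#' Export NBS components as a TSV edge table
#'
#' Columns: region1, region2, t, component_id, corrected_p (the layout of a
#' significant-connections table).
#'
#' @param result an `nbs_result`.
#' @param path output file, or `NULL` to just return the data.frame.
#' @return the data.frame, invisibly when written.
#' @export
nbs_edge_table <- function(result, path = NULL) {
  rows <- list()
  for (k in seq_along(result$components)) {
    cc <- result$components[[k]]
    rows[[k]] <- data.frame(
      region1 = result$region_labels[cc$edges[, 1]],
      region2 = result$region_labels[cc$edges[, 2]],
      t = cc$t_values, component_id = k, corrected_p = cc$corrected_p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region1 = character(0), region2 = character(0),
               t = numeric(0), component_id = integer(0),
               corrected_p = numeric(0))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
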