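mk_conn <- function(z) {
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(list(z_matrix = z,
                 region_labels = sprintf("R%02d", seq_len(ncol(z)))),
            class = "connectome")
}

toy_design <- function(n_pat, n_ctl, covariates = FALSE, seed = 1) {
  set.seed(seed)
  n <- n_pat + n_ctl
  man <- data.frame(subject_id = sprintf("s%02d", 1:n),
                    group = rep(c("patient", "control"), c(n_pat, n_ctl)),
                    age = rnorm(n, 50, 8), sex = sample(c("M", "F"), n, TRUE),
                    education = rnorm(n, 12, 2),
                    mean_fd = runif(n, 0.05, 0.2))
  design_matrix(man, covariates = if (covariates)
    c("age", "sex", "education", "mean_fd") else character(0))
}

test_that("identical groups produce an empty supra-threshold graph", {
  set.seed(2)
  zs <- lapply(1:4, function(i) matrix(rnorm(36), 6))
  z_list <- lapply(c(zs, zs), mk_conn)      # patients and controls identical
  X <- toy_design(4, 4)
  m <- edge_t_map(z_list, X, tail = "patient_gt", primary_t = 0.5)
  expect_equal(sum(m$supra_adjacency), 0)
  m2 <- edge_t_map(z_list, X, tail = "patient_lt", primary_t = 0.5)
  expect_equal(sum(m2$supra_adjacency), 0)
})

test_that("edge t values equal the per-edge GLM t", {
  set.seed(6)
  z_list <- lapply(1:12, function(i) mk_conn(matrix(rnorm(36), 6)))
  X <- toy_design(6, 6, covariates = TRUE, seed = 3)
  m <- edge_t_map(z_list, X, tail = "patient_gt", primary_p = 0.01)
  ut <- which(upper.tri(m$t_matrix), arr.ind = TRUE)
  for (r in seq_len(nrow(ut))) {
    y <- vapply(z_list, function(cc) cc$z_matrix[ut[r, 1], ut[r, 2]],
                numeric(1))
    expect_equal(m$t_matrix[ut[r, 1], ut[r, 2]],
                 glm_group_t(y, X)$t_value, tolerance = 1e-10)
  }
  expect_equal(m$primary_threshold, qt(1 - 0.01 / 2, m$df))
})

test_that("component extraction matches a union-find oracle", {
  a <- adj_from_edges(5, list(c(1, 2), c(2, 3), c(4, 5)))
  comps <- supra_components(a)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, integer(1), "size_in_edges"), c(2L, 1L))
  expect_setequal(comps[[1]]$nodes, 1:3)

  expect_length(supra_components(matrix(0, 4, 4)), 0)

  set.seed(14)
  for (rep in 1:30) {
    adj <- rand_adj(10, runif(1, 0.05, 0.3))
    sizes <- vapply(supra_components(adj), `[[`, integer(1), "size_in_edges")
    expect_equal(sort(sizes, decreasing = TRUE), uf_component_edge_sizes(adj))
  }
})

test_that("permutation p-values use the +1 convention and decrease with size", {
  set.seed(10)
  base <- matrix(rnorm(100, sd = 0.1), 10)
  z_list <- lapply(1:14, function(i) {
    z <- base + matrix(rnorm(100, sd = 0.1), 10)
    if (i <= 7) z[1, 2] <- z[2, 1] <- z[1, 2] + 3   # strong planted edge
    mk_conn(z)
  })
  X <- toy_design(7, 7, seed = 5)
  res <- nbs_permutation_test(z_list, X, tail = "patient_gt",
                              primary_p = 0.01, n_permutations = 200,
                              seed = 77)
  expect_gt(length(res$components), 0)
  ps <- vapply(res$components, `[[`, numeric(1), "corrected_p")
  szs <- vapply(res$components, `[[`, integer(1), "size_in_edges")
  expect_true(all(ps > 0))
  expect_true(all(ps <= 1))
  expect_gte(min(ps), 1 / (res$n_permutations + 1))
  # ordered by decreasing size; corrected p must be non-decreasing
  expect_true(all(diff(szs) <= 0))
  expect_true(all(diff(ps) >= 0))
  # identity permutation reproduces the observed max component size
  m <- edge_t_map(z_list, X, tail = "patient_gt", primary_p = 0.01)
  obs_max <- max(szs)
  expect_equal(fconn:::max_component_size(m$supra_adjacency), obs_max)

  expect_error(nbs_permutation_test(z_list, X, n_permutations = 50),
               ">= 100")
})

test_that("NBS results are invariant to node relabeling", {
  set.seed(20)
  z_raw <- lapply(1:10, function(i) {
    z <- matrix(rnorm(64, sd = 0.2), 8)
    if (i <= 5) z[3, 4] <- z[4, 3] <- z[3, 4] + 2.5
    (z + t(z)) / 2
  })
  X <- toy_design(5, 5, seed = 8)
  base <- nbs_permutation_test(lapply(z_raw, mk_conn), X,
                               tail = "patient_gt", primary_p = 0.05,
                               n_permutations = 150, seed = 4)
  base_sizes <- sort(vapply(base$components, `[[`, integer(1),
                            "size_in_edges"))
  base_ps <- sort(vapply(base$components, `[[`, numeric(1), "corrected_p"))
  set.seed(30)
  for (rep in 1:10) {
    perm <- sample(8)
    res <- nbs_permutation_test(lapply(z_raw, function(z)
      mk_conn(z[perm, perm])), X, tail = "patient_gt", primary_p = 0.05,
      n_permutations = 150, seed = 4)
    expect_equal(sort(vapply(res$components, `[[`, integer(1),
                             "size_in_edges")), base_sizes)
    expect_equal(sort(vapply(res$components, `[[`, numeric(1),
                             "corrected_p")), base_ps)
  }
})

test_that("planted edges rank in the top decile of edge statistics", {
  coh <- generate_cohort(cohort_spec(seed = 31))
  subs <- lapply(coh$subjects, preprocess_subject)
  conns <- lapply(subs, function(s) build_connectome(s$timeseries))
  man <- cohort_manifest(coh)
  man$mean_fd <- vapply(subs, `[[`, numeric(1), "mean_fd")
  X <- design_matrix(man)
  m <- edge_t_map(conns, X, tail = "patient_gt", primary_p = 0.01)
  pe <- default_planted_edges()
  abs_t <- abs(m$t_matrix[upper.tri(m$t_matrix)])
  planted_t <- abs(m$t_matrix[cbind(pe$i, pe$j)])
  q90 <- quantile(abs_t, 0.9)
  expect_gte(mean(planted_t > q90), 0.8)
})

test_that("NBS component tables export in the expected layout", {
  set.seed(44)
  z_list <- lapply(1:10, function(i) {
    z <- matrix(rnorm(49, sd = 0.2), 7)
    if (i <= 5) z[1, 2] <- z[2, 1] <- z[1, 2] + 2.5
    mk_conn(z)
  })
  X <- toy_design(5, 5, seed = 9)
  res <- nbs_permutation_test(z_list, X, tail = "patient_gt",
                              primary_p = 0.05, n_permutations = 150,
                              seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- nbs_edge_table(res, path)
  expect_true(file.exists(path))
  got <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(got), c("region1", "region2", "t", "component_id",
                             "corrected_p"))
})
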