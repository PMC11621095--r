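# Covariate-adjusted two-sample inference on AUC metrics.

#' Group design matrix
#'
#' Intercept, binary group indicator (patient = 1), and mean-centered
#' covariates (age, sex coded 0/1, education in years, mean FD). Centering
#' does not change the group t statistic but improves conditioning.
#'
#' @param manifest data.frame with columns `subject_id`, `group`
#'   (patient/control) and the requested covariates (`sex` may be a
#'   character/factor with two levels).
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @return numeric matrix with rownames = subject ids and a `group` column;
#'   class `fconn_design`.
#' @export
design_matrix <- function(manifest,
                          covariates = c("age", "sex", "education",
                                         "mean_fd")) {
  stopifnot(all(c("subject_id", "group") %in% names(manifest)))
  if (!all(manifest$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  X <- cbind(intercept = rep(1, nrow(manifest)),
             group = as.numeric(manifest$group == "patient"))
  for (cv in covariates) {
    if (!cv %in% names(manifest))
      stop("covariate '", cv, "' missing from manifest")
    v <- manifest[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, scale(v, scale = FALSE)[, 1])
    colnames(X)[ncol(X)] <- cv
  }
  rownames(X) <- manifest$subject_id
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  class(X) <- c("fconn_design", "matrix")
  X
}

#' Covariate-adjusted group t test (GLM)
#'
#' Ordinary-least-squares fit of the outcome on the design; the statistic is
#' the group-column coefficient divided by its standard error, with a
#' two-tailed p from the t distribution on `n - p` degrees of freedom. With no
#' covariate columns this reduces exactly to the classical pooled two-sample
#' t test. A zero-variance outcome yields t = 0, p = 1 with a warning.
#'
#' @param y numeric outcome vector (one value per design row).
#' @param design a [design_matrix()].
#' @return one-row data.frame: estimate, t_value, p_value, df.
#' @export
glm_group_t <- function(y, design) {
  X <- unclass(design)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("outcome length does not match design rows")
  if (any(!is.finite(y))) stop("outcome contains non-finite values")
  df <- n - p
  if (df < 1) stop("not enough residual degrees of freedom")
  if (stats::var(y) == 0) {
    warning("zero-variance outcome; returning t = 0, p = 1")
    return(data.frame(estimate = 0, t_value = 0, p_value = 1, df = df))
  }
  fit <- stats::lm(y ~ 0 + X)
  cf <- stats::coef(summary(fit))
  row <- cf["Xgroup", ]
  data.frame(estimate = unname(row["Estimate"]),
             t_value = unname(row["t value"]),
             p_value = unname(row["Pr(>|t|)"]), df = df)
}

# align an AUC sub-table to the design's subject order
auc_vector <- function(auc_tab, design, metric, node = "global") {
  d <- auc_tab[auc_tab$metric == metric & auc_tab$node == node, ]
  if (nrow(d) == 0) stop("metric '", metric, "' (node ", node,
                         ") missing from AUC table")
  idx <- match(rownames(design), d$subject_id)
  if (any(is.na(idx))) stop("AUC table missing subjects present in design")
  d$auc[idx]
}

#' Group tests on global metric AUCs
#'
#' One uncorrected covariate-adjusted t test per global metric; significance
#' at `p < alpha`.
#'
#' @param auc_tab an [auc_table()].
#' @param design a [design_matrix()].
#' @param metrics global metrics to test; all must be present.
#' @param alpha significance level (default 0.05).
#' @return data.frame: metric, node, estimate, t_value, p_value, df,
#'   significant, correction.
#' @export
test_global <- function(auc_tab, design,
                        metrics = c("Cp", "Lp", "gamma", "lambda", "sigma",
                                    "Eglob", "Eloc"),
                        alpha = 0.05) {
  out <- do.call(rbind, lapply(metrics, function(m) {
    r <- glm_group_t(auc_vector(auc_tab, design, m), design)
    cbind(data.frame(metric = m, node = "global", stringsAsFactors = FALSE), r)
  }))
  out$significant <- out$p_value < alpha
  out$correction <- "none"
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected group tests on nodal metric AUCs
#'
#' Per metric, one covariate-adjusted t test per node; the Bonferroni family
#' is the number of nodes within each metric (90 for the AAL atlas), so a node
#' is significant iff `p < alpha / family`.
#'
#' @inheritParams test_global
#' @param metrics nodal metrics to test.
#' @param family Bonferroni family size; defaults to the number of nodes per
#'   metric.
#' @return data.frame: metric, node, estimate, t_value, p_value, df,
#'   significant, correction.
#' @export
test_nodal <- function(auc_tab, design,
                       metrics = c("degree", "efficiency", "betweenness",
                                   "local_efficiency"),
                       alpha = 0.05, family = NULL) {
  out <- do.call(rbind, lapply(metrics, function(m) {
    d <- auc_tab[auc_tab$metric == m & auc_tab$node != "global", ]
    if (nrow(d) == 0) stop("nodal metric '", m, "' missing from AUC table")
    nodes <- unique(d$node)
    fam <- family %||% length(nodes)
    res <- do.call(rbind, lapply(nodes, function(nd) {
      r <- glm_group_t(auc_vector(auc_tab, design, m, nd), design)
      cbind(data.frame(metric = m, node = nd, stringsAsFactors = FALSE), r)
    }))
    res$significant <- res$p_value < alpha / fam
    res$correction <- "bonferroni"
    res
  }))
  rownames(out) <- NULL
  out
}
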