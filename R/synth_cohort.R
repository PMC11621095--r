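# Synthetic two-group cohort generator.
#
# Latent-signal model: every region's series is a linear mix of band-limited
# Gaussian latent processes --
#   x_i = cw * M[module(i)] + cl * L_i + cb * G + sum_e ce * P_e + noise_sd * eps_i
# where M are module signals (modules interleaved over the region index, so
# module edges act as long-range shortcuts), L_i is a ring-lattice
# neighbourhood field (kernel-smoothed white latents, giving correlations that
# decay with region-index distance and hence clustered lattice edges), G is a
# global signal, and P_e are per-planted-edge shared latents. The mix is then
# band-limited to the analysis band with the same filter the preprocessing
# module exposes. Covariance is positive semi-definite by construction
# (explicit factor model).

default_module_assignment <- function(n_regions = 90L, n_modules = 6L) {
  ((seq_len(n_regions) - 1L) %% n_modules) + 1L
}

#' Default planted-edge set
#'
#' Fifteen region pairs (AAL indices) forming two clusters of altered
#' functional connections: five occipito-parietal pairs coupled only in the
#' patient group (increased connectivity) and ten fronto-temporal pairs
#' coupled only in the control group (decreased connectivity in patients).
#'
#' @param coupling latent coupling of the affected group on each planted edge.
#' @return data.frame with columns `i`, `j`, `coupling_patient`,
#'   `coupling_control`.
#' @export
default_planted_edges <- function(coupling = 0.65) {
  up <- rbind(c(49, 53), c(49, 54), c(53, 67), c(55, 67), c(56, 67))
  dn <- rbind(c(11, 15), c(14, 16), c(14, 55), c(11, 56), c(12, 56),
              c(13, 56), c(14, 56), c(12, 85), c(12, 86), c(14, 90))
  data.frame(i = c(up[, 1], dn[, 1]), j = c(up[, 2], dn[, 2]),
             coupling_patient = c(rep(coupling, nrow(up)), rep(0, nrow(dn))),
             coupling_control = c(rep(0, nrow(up)), rep(coupling, nrow(dn))))
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study conditions of the emulated two-group design:
#' 30 patients vs 24 controls, 90 AAL regions, 400 volumes at TR = 1 s,
#' band-limited signal in 0.01-0.08 Hz, modular covariance with a patient-group
#' reduction of within-module coupling, a planted set of altered edges, and a
#' planted nodal deficit at the right amygdala (region 42).
#'
#' @param n_patients,n_controls group sizes.
#' @param n_regions,n_volumes,tr_seconds acquisition geometry.
#' @param module_assignment integer vector mapping region -> module id;
#'   default interleaves 6 modules over the region index.
#' @param within_module_coupling named numeric `c(control=, patient=)` in
#'   `[0,1)`: coupling of each region to its module signal.
#' @param between_module_coupling coupling to the shared global signal.
#' @param lattice_coupling,lattice_length coupling to (and Gaussian-kernel
#'   length of) the ring-lattice neighbourhood field; the coupling may be a
#'   scalar or a named per-group vector like `within_module_coupling`.
#' @param planted_edges data.frame as in [default_planted_edges()], or `NULL`.
#' @param planted_node region index receiving a neighbourhood-decoupling
#'   effect in the patient group (`NULL` to disable). The node anchors a
#'   small clustered neighbourhood (a shared hub latent over the node and its
#'   ring neighbours within distance 2) present in both groups.
#' @param planted_node_attenuation multiplier (< 1) applied to the planted
#'   node's structural couplings -- including its hub coupling -- in
#'   patients, decoupling it from its neighbourhood.
#' @param planted_hub_coupling coupling of the planted node's neighbourhood
#'   to the shared hub latent.
#' @param noise_sd standard deviation of independent region noise.
#' @param motion_scale stationary amplitude (mm) of the simulated head-motion
#'   random walk; rotations scale as `motion_scale / 50` radians.
#' @param band analysis frequency band (Hz) used to band-limit the signal.
#' @param seed master integer seed; all randomness derives from it.
#' @return a validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 30L, n_controls = 24L, n_regions = 90L,
                        n_volumes = 400L, tr_seconds = 1.0,
                        module_assignment = NULL,
                        within_module_coupling = c(control = 0.51,
                                                   patient = 0.455),
                        between_module_coupling = 0.18,
                        lattice_coupling = c(control = 0.62,
                                             patient = 0.575),
                        lattice_length = 1.6,
                        planted_edges = default_planted_edges(),
                        planted_node = 42L,
                        planted_node_attenuation = 0,
                        planted_hub_coupling = 0.8,
                        noise_sd = 0.5, motion_scale = 0.2,
                        band = c(0.01, 0.08), seed = 1L) {
  if (is.null(module_assignment))
    module_assignment <- default_module_assignment(n_regions)
  spec <- structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds, module_assignment = as.integer(module_assignment),
    within_module_coupling = within_module_coupling,
    between_module_coupling = between_module_coupling,
    lattice_coupling = lattice_coupling, lattice_length = lattice_length,
    planted_edges = planted_edges,
    planted_node = if (is.null(planted_node)) NULL else as.integer(planted_node),
    planted_node_attenuation = planted_node_attenuation,
    planted_hub_coupling = planted_hub_coupling,
    noise_sd = noise_sd, motion_scale = motion_scale,
    band = band, seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_patients >= 1, n_controls >= 1, n_regions >= 2)
    if (n_volumes <= 10)
      stop("n_volumes must exceed 10 (the discarded lead-in)")
    if (length(module_assignment) != n_regions)
      stop("module_assignment must map every region to a module")
    if (!all(c("control", "patient") %in% names(within_module_coupling)))
      stop("within_module_coupling needs named 'control' and 'patient' entries")
    cps <- c(within_module = within_module_coupling,
             between_module = between_module_coupling,
             lattice = lattice_coupling,
             planted_hub = planted_hub_coupling)
    bad <- cps < 0 | cps >= 1
    if (any(bad))
      stop("couplings outside [0,1) do not define a positive semi-definite ",
           "latent covariance: ",
           paste(sprintf("%s = %.3f", names(cps)[bad], cps[bad]),
                 collapse = ", "))
    if (!is.null(planted_edges) && nrow(planted_edges)) {
      if (!all(c("i", "j", "coupling_patient", "coupling_control") %in%
               names(planted_edges)))
        stop("planted_edges needs columns i, j, coupling_patient, coupling_control")
      idx <- c(planted_edges$i, planted_edges$j)
      if (any(idx < 1 | idx > n_regions) || any(planted_edges$i == planted_edges$j))
        stop("planted_edges reference invalid region indices")
      pc <- c(planted_edges$coupling_patient, planted_edges$coupling_control)
      if (any(pc < 0 | pc >= 1))
        stop("planted edge couplings outside [0,1) do not define a positive ",
             "semi-definite latent covariance")
    }
    if (!is.null(planted_node) &&
        (planted_node < 1 || planted_node > n_regions))
      stop("planted_node out of range")
    stopifnot(noise_sd >= 0, motion_scale >= 0,
              planted_node_attenuation >= 0, planted_node_attenuation <= 1)
  })
  invisible(spec)
}

# circulant ring kernel with unit-norm columns: lattice field L = U %*% K
ring_kernel <- function(n_regions, lattice_length) {
  idx <- seq_len(n_regions)
  d <- outer(idx, idx, function(a, b) pmin(abs(a - b), n_regions - abs(a - b)))
  K <- exp(-d^2 / (2 * lattice_length^2))
  K[d > ceiling(3 * lattice_length)] <- 0
  sweep(K, 2, sqrt(colSums(K^2)), "/")
}

#' Simulate one subject's head-motion trace
#'
#' Bounded (stationary AR(1)) random walk: translations with stationary
#' standard deviation `motion_scale` mm, rotations with `motion_scale / 50`
#' radians, per volume. Deterministic given `spec$seed` and the subject index.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject position in the cohort.
#' @return volumes x 6 matrix (3 translations mm, 3 rotations radians).
#' @export
generate_motion <- function(spec, subject_index) {
  stopifnot(spec$n_volumes >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, 100000 + subject_index))
  phi <- 0.98
  n <- spec$n_volumes
  sds <- c(rep(spec$motion_scale, 3), rep(spec$motion_scale / 50, 3))
  out <- vapply(sds, function(s) {
    innov <- stats::rnorm(n, sd = s * sqrt(1 - phi^2))
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }, numeric(n))
  colnames(out) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

group_coupling <- function(x, group) {
  if (length(x) == 1 && is.null(names(x))) unname(x)
  else unname(x[group])
}

# neighbourhood anchored at the planted node: ring neighbours within
# distance 2 plus the nearest same-module partners (distance 6), so the hub
# clique mixes local and shortcut edges
hub_members <- function(spec) {
  n <- spec$n_regions
  unique(((spec$planted_node - 1 + c(-2, -1, 0, 1, 2)) %% n) + 1)
}

subject_couplings <- function(spec, group) {
  n <- spec$n_regions
  cw <- rep(group_coupling(spec$within_module_coupling, group), n)
  cl <- rep(group_coupling(spec$lattice_coupling, group), n)
  cb <- rep(spec$between_module_coupling, n)
  if (!is.null(spec$planted_node) && group == "patient") {
    a <- spec$planted_node_attenuation
    cw[spec$planted_node] <- cw[spec$planted_node] * a
    cl[spec$planted_node] <- cl[spec$planted_node] * a
    cb[spec$planted_node] <- cb[spec$planted_node] * a
  }
  list(cw = cw, cl = cl, cb = cb)
}

generate_subject_timeseries <- function(spec, group, subject_seed, kernel) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed)
  T <- spec$n_volumes
  n <- spec$n_regions
  mods <- spec$module_assignment
  n_mod <- max(mods)
  M <- matrix(stats::rnorm(T * n_mod), T, n_mod)
  L <- matrix(stats::rnorm(T * n), T, n) %*% kernel
  G <- stats::rnorm(T)
  E <- matrix(stats::rnorm(T * n), T, n)
  cp <- subject_couplings(spec, group)
  X <- M[, mods, drop = FALSE] * rep(cp$cw, each = T) +
       L * rep(cp$cl, each = T) +
       G %o% cp$cb +
       spec$noise_sd * E
  if (!is.null(spec$planted_node) && spec$planted_hub_coupling > 0) {
    hub <- hub_members(spec)
    H <- stats::rnorm(T)
    ch <- rep(spec$planted_hub_coupling, length(hub))
    if (group == "patient")
      ch[hub == spec$planted_node] <- ch[hub == spec$planted_node] *
        spec$planted_node_attenuation
    X[, hub] <- X[, hub] + H %o% ch
  }
  pe <- spec$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    cc <- if (group == "patient") pe$coupling_patient else pe$coupling_control
    for (e in seq_len(nrow(pe))) {
      if (cc[e] == 0) next
      P <- stats::rnorm(T)
      X[, pe$i[e]] <- X[, pe$i[e]] + cc[e] * P
      X[, pe$j[e]] <- X[, pe$j[e]] + cc[e] * P
    }
  }
  labels <- if (n == 90) aal90_regions()$abbrev else sprintf("R%03d", 1:n)
  ts <- roi_timeseries(X, labels, spec$tr_seconds)
  ts <- bandpass(ts, spec$band[1], spec$band[2])
  # unit-variance regions; correlations are unaffected
  sds <- apply(ts$values, 2, stats::sd)
  sds[sds == 0] <- 1
  roi_timeseries(sweep(ts$values, 2, sds, "/"), labels, spec$tr_seconds)
}

generate_covariates <- function(group) {
  # synthetic demographics echoing the emulated cohort (patients older);
  # used only to exercise covariate adjustment
  if (group == "patient") age <- stats::rnorm(1, 54.56, 9.91)
  else age <- stats::rnorm(1, 42.45, 10.18)
  list(age = round(age, 1),
       sex = sample(c("M", "F"), 1),
       education = round(max(stats::rnorm(1, 12, 3), 3)))
}

#' Generate a synthetic two-group cohort
#'
#' Deterministic given `spec$seed`: per subject, regional series are linear
#' mixes of shared band-limited latent signals (module, ring-lattice
#' neighbourhood, global, planted-edge) plus independent noise, band-limited
#' to the analysis band; the patient group uses a lower within-module coupling
#' and the planted edge/node effects.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `fconn_cohort`: list with `subjects` (each a
#'   list with `subject_id`, `group`, `age`, `sex`, `education`, `timeseries`,
#'   `motion`) and the generating `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  kernel <- ring_kernel(spec$n_regions, spec$lattice_length)
  n_total <- spec$n_patients + spec$n_controls
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    group <- if (i <= spec$n_patients) "patient" else "control"
    sseed <- derive_seed(spec$seed, i)
    ts <- generate_subject_timeseries(spec, group, sseed, kernel)
    old <- .Random.seed_save()
    set.seed(derive_seed(spec$seed, 200000 + i))
    cov <- generate_covariates(group)
    .Random.seed_restore(old)
    subjects[[i]] <- c(list(subject_id = sprintf("sub-%03d", i),
                            group = group),
                       cov,
                       list(timeseries = ts,
                            motion = generate_motion(spec, i)))
  }
  structure(list(subjects = subjects, spec = spec,
                 covariate_model = paste(
                   "age ~ N(54.56, 9.91) patients / N(42.45, 10.18) controls;",
                   "sex ~ Bernoulli(0.5); education ~ N(12, 3) years",
                   "(synthetic, for covariate-adjustment exercises only)")),
            class = "fconn_cohort")
}

#' @export
print.fconn_cohort <- function(x, ...) {
  cat("<fconn_cohort> ", x$spec$n_patients, " patients + ",
      x$spec$n_controls, " controls, ", x$spec$n_regions, " regions x ",
      x$spec$n_volumes, " volumes (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Cohort manifest
#'
#' @param cohort an `fconn_cohort`.
#' @return data.frame: subject_id, group, age, sex, education (one row per
#'   subject, in cohort order).
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, education = s$education,
               stringsAsFactors = FALSE)))
}

#' Write a cohort to disk
#'
#' One whitespace-delimited time-series matrix and one 6-column motion file
#' per subject, plus a TSV manifest with group, covariates and file paths.
#'
#' @param cohort an `fconn_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort_manifest(cohort)
  man$timeseries_file <- file.path(dir, paste0(man$subject_id, "_ts.tsv"))
  man$motion_file <- file.path(dir, paste0(man$subject_id, "_motion.tsv"))
  for (k in seq_along(cohort$subjects)) {
    write_roi_ts(cohort$subjects[[k]]$timeseries, man$timeseries_file[k])
    write_matrix_tsv(cohort$subjects[[k]]$motion, man$motion_file[k])
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}
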