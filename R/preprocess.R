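# ROI-level denoising: volume discard, motion QC via framewise displacement,
# nuisance regression (detrend + Friston-24 + global signal), band-pass.

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes (default 10, leaving 390 of a 400-volume
#' acquisition) to remove the pre-steady-state signal.
#'
#' @param ts an [roi_timeseries()] object.
#' @param n_discard number of leading volumes to drop; must be smaller than the
#'   number of volumes.
#' @return an `roi_ts` with the leading rows removed.
#' @export
discard_initial_volumes <- function(ts, n_discard = 10L) {
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stop("n_discard must be >= 0")
  if (n_discard >= n_volumes(ts))
    stop("n_discard (", n_discard, ") must be smaller than the volume count (",
         n_volumes(ts), ")")
  if (n_discard == 0) return(ts)
  roi_timeseries(ts$values[-seq_len(n_discard), , drop = FALSE],
                 ts$region_labels, ts$tr_seconds)
}

check_motion <- function(motion) {
  motion <- as.matrix(motion)
  storage.mode(motion) <- "double"
  if (ncol(motion) != 6)
    stop("motion must have 6 columns (3 translations in mm, 3 rotations in ",
         "radians); got ", ncol(motion))
  motion
}

#' Framewise displacement
#'
#' Power-style FD: the sum of absolute inter-volume changes of the six
#' rigid-body parameters, with rotations converted to arc displacement on a
#' 50 mm sphere. `FD[1] = 0`.
#'
#' @param motion volumes x 6 matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations (radians).
#' @param sphere_radius_mm radius used to convert rotation angles to
#'   displacements (mm).
#' @return numeric vector of per-volume FD values (mm).
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  motion <- check_motion(motion)
  if (nrow(motion) < 2) stop("motion must have at least 2 volumes")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
       sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' @rdname framewise_displacement
#' @export
mean_fd <- function(motion, sphere_radius_mm = 50) {
  mean(framewise_displacement(motion, sphere_radius_mm))
}

#' Head-motion quality control
#'
#' A subject fails QC when the maximum absolute translation exceeds
#' `max_translation_mm` on any axis or the maximum absolute rotation exceeds
#' `max_rotation_deg` on any axis (defaults 1.5 mm and 1.5 degrees).
#'
#' @inheritParams framewise_displacement
#' @param max_translation_mm,max_rotation_deg exclusion bounds.
#' @return list with elements `pass` (logical), `reason` (character, `""` when
#'   passing), `max_translation_mm`, `max_rotation_deg`, `mean_fd`.
#' @export
qc_exclude <- function(motion, max_translation_mm = 1.5,
                       max_rotation_deg = 1.5) {
  motion <- check_motion(motion)
  trans <- abs(motion[, 1:3, drop = FALSE])
  rot_deg <- abs(motion[, 4:6, drop = FALSE]) * 180 / pi
  axes_t <- c("x", "y", "z")
  axes_r <- c("pitch", "roll", "yaw")
  it <- arrayInd(which.max(trans), dim(trans))
  ir <- arrayInd(which.max(rot_deg), dim(rot_deg))
  max_t <- trans[it]
  max_r <- rot_deg[ir]
  reason <- ""
  if (max_t > max_translation_mm)
    reason <- sprintf("translation %s = %.3f mm exceeds %.2f mm",
                      axes_t[it[2]], max_t, max_translation_mm)
  else if (max_r > max_rotation_deg)
    reason <- sprintf("rotation %s = %.3f deg exceeds %.2f deg",
                      axes_r[ir[2]], max_r, max_rotation_deg)
  list(pass = reason == "", reason = reason,
       max_translation_mm = max_t, max_rotation_deg = max_r,
       mean_fd = if (nrow(motion) >= 2) mean_fd(motion) else 0)
}

#' Friston 24-parameter motion expansion
#'
#' The six rigid-body parameters, their one-volume lags, and the squares of
#' both (6 + 6 + 6 + 6 = 24 columns).
#'
#' @inheritParams framewise_displacement
#' @return volumes x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- check_motion(motion)
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_lag"),
                     paste0("mp", 1:6, "_sq"), paste0("mp", 1:6, "_lagsq"))
  out
}

#' Build a nuisance regression design
#'
#' Intercept and linear trend are always included (linear detrending); the
#' Friston-24 motion expansion, the global signal (mean over the regional
#' series), and mean FD can be added.
#'
#' @param n_volumes number of (post-discard) volumes the design must cover.
#' @param motion optional volumes x 6 motion matrix (post-discard rows).
#' @param global_signal optional numeric vector (e.g. `rowMeans` of the ROI
#'   matrix).
#' @param include_friston24,include_mean_fd logical switches.
#' @return list with `regressors` (volumes x k matrix) and `column_names`.
#' @export
nuisance_model <- function(n_volumes, motion = NULL, global_signal = NULL,
                           include_friston24 = !is.null(motion),
                           include_mean_fd = FALSE) {
  X <- cbind(intercept = rep(1, n_volumes),
             trend = seq_len(n_volumes) - (n_volumes + 1) / 2)
  if (!is.null(motion)) {
    motion <- check_motion(motion)
    if (nrow(motion) != n_volumes)
      stop("motion has ", nrow(motion), " rows; expected ", n_volumes)
    if (include_friston24) X <- cbind(X, friston24(motion))
    if (include_mean_fd)
      X <- cbind(X, fd = framewise_displacement(motion))
  }
  if (!is.null(global_signal)) {
    if (length(global_signal) != n_volumes)
      stop("global_signal length mismatch")
    X <- cbind(X, global = as.numeric(global_signal))
  }
  list(regressors = X, column_names = colnames(X))
}

# drop exactly collinear columns (zero or duplicated directions), keeping the
# leading intercept/trend block; errors if the pruned design is still
# rank-deficient at working precision
prune_design <- function(X) {
  qrX <- qr(X, tol = 1e-9)
  if (qrX$rank == ncol(X)) return(list(X = X, dropped = character(0)))
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  Xp <- X[, keep, drop = FALSE]
  if (qr(Xp, tol = 1e-9)$rank < ncol(Xp))
    stop("nuisance design rank-deficient after pruning; dropped columns: ",
         paste(dropped, collapse = ", "))
  list(X = Xp, dropped = dropped)
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary-least-squares residuals of each regional series on the nuisance
#' design. Exactly collinear design columns are dropped with a message.
#'
#' @param ts an `roi_ts`.
#' @param model a [nuisance_model()].
#' @return an `roi_ts` of residuals (same shape and labels).
#' @export
regress_nuisance <- function(ts, model) {
  X <- model$regressors
  if (nrow(X) != n_volumes(ts))
    stop("design rows (", nrow(X), ") do not match volumes (",
         n_volumes(ts), ")")
  pr <- prune_design(X)
  if (length(pr$dropped))
    message("dropped exactly collinear nuisance columns: ",
            paste(pr$dropped, collapse = ", "))
  res <- stats::lm.fit(pr$X, ts$values)$residuals
  roi_timeseries(as.matrix(res), ts$region_labels, ts$tr_seconds)
}

#' Temporal band-pass filter
#'
#' Ideal (boxcar) frequency-domain filter: Fourier components with frequency
#' outside `[low_hz, high_hz]` are zeroed. With the default band
#' (0.01-0.08 Hz) the DC component is removed, so the output is zero-mean.
#'
#' @param ts an `roi_ts`.
#' @param low_hz,high_hz band edges in Hz; require
#'   `0 <= low_hz < high_hz < 0.5 / tr_seconds` (Nyquist).
#' @return a filtered `roi_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  nyquist <- 0.5 / ts$tr_seconds
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist)
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency (",
         nyquist, " Hz)")
  n <- n_volumes(ts)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) / (n * ts$tr_seconds)
  keep <- freq >= low_hz & freq <= high_hz
  xf <- stats::mvfft(ts$values)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  roi_timeseries(out, ts$region_labels, ts$tr_seconds)
}

#' Preprocess one subject record
#'
#' Runs the ROI-level chain in the fixed order discard -> nuisance
#' regression/detrend -> band-pass, and attaches the mean FD (computed on the
#' post-discard motion) as a subject-level covariate.
#'
#' @param record a subject record from [generate_cohort()] (fields
#'   `timeseries`, `motion`).
#' @param n_discard leading volumes to drop.
#' @param band length-2 numeric, band-pass edges in Hz.
#' @param include_friston24,include_global_signal,include_mean_fd nuisance
#'   design switches; mean FD is by default used only as a group-level
#'   covariate, not a subject-level regressor.
#' @return the record with `timeseries` replaced by its preprocessed version
#'   and a `mean_fd` field added.
#' @export
preprocess_subject <- function(record, n_discard = 10L, band = c(0.01, 0.08),
                               include_friston24 = TRUE,
                               include_global_signal = TRUE,
                               include_mean_fd = FALSE) {
  ts <- discard_initial_volumes(record$timeseries, n_discard)
  motion <- check_motion(record$motion)
  motion_pd <- motion[-seq_len(n_discard), , drop = FALSE]
  if (n_discard == 0) motion_pd <- motion
  gs <- if (include_global_signal) rowMeans(ts$values) else NULL
  model <- nuisance_model(n_volumes(ts), motion = motion_pd,
                          global_signal = gs,
                          include_friston24 = include_friston24,
                          include_mean_fd = include_mean_fd)
  ts <- regress_nuisance(ts, model)
  ts <- bandpass(ts, band[1], band[2])
  record$timeseries <- ts
  record$mean_fd <- mean_fd(motion_pd)
  record
}
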