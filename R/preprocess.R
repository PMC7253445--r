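# Run-wise preprocessing for background connectivity: nuisance + task-evoked
# regression, zero-phase bandpass filtering and spatial smoothing.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at 6 s, undershoot
#' peak at 16 s and undershoot ratio 1/6, sampled at the repetition time and
#' normalized to unit peak.
#'
#' @param tr_s Sampling interval in seconds.
#' @param duration_s Kernel length in seconds.
#' @param peak_s,undershoot_s Peak delays of response and undershoot.
#' @param ratio Undershoot amplitude relative to the response peak.
#' @return Numeric vector of kernel samples at `t = 0, tr_s, 2 tr_s, ...`.
#' @export
hrf_double_gamma <- function(tr_s, duration_s = 32, peak_s = 6,
                             undershoot_s = 16, ratio = 1 / 6) {
  stopifnot(tr_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  # gamma density parameterized by peak p and dispersion 1: shape p + 1, scale 1
  g <- function(t, p) stats::dgamma(t, shape = p + 1, scale = 1)
  h <- g(t, peak_s) - ratio * g(t, undershoot_s)
  h / max(h)
}

# Boxcar (one entry per TR sample, fraction of the TR during which a stimulus
# is on) over a run, from session-clock events.
run_boxcar <- function(task, run_index, run_start_s, n_samp, tr_s) {
  box <- numeric(n_samp)
  ev <- task$events[task$events$run == run_index, , drop = FALSE]
  if (nrow(ev) == 0) return(box)
  edges <- run_start_s + (seq_len(n_samp + 1) - 1) * tr_s
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset_s[i]
    off <- on + ev$duration_s[i]
    overlap <- pmax(0, pmin(off, edges[-1]) - pmax(on, edges[-length(edges)]))
    box <- box + overlap / tr_s
  }
  pmin(box, 1)
}

# Backward-difference temporal derivative, first element 0 (length-preserving).
temporal_derivative <- function(x) {
  x <- as.matrix(x)
  rbind(0, diff(x))
}

# Per-run nuisance + task design matrix (including intercept).
build_design <- function(conf, task, run_index, rows, run_start_s, tr_s) {
  n <- length(rows)
  mot <- conf$motion6[rows, , drop = FALSE]
  nuis <- cbind(mot, conf$wm[rows], conf$csf[rows], conf$global[rows])
  colnames(nuis) <- c(paste0("mot", 1:6), "wm", "csf", "global")
  dnuis <- temporal_derivative(nuis)
  colnames(dnuis) <- paste0("d_", colnames(nuis))
  X <- cbind(intercept = 1, nuis, dnuis)
  if (!is.null(conf$outliers)) {
    out <- conf$outliers[rows, , drop = FALSE]
    keep <- colSums(out != 0) > 0
    if (any(keep)) {
      out <- out[, keep, drop = FALSE]
      colnames(out) <- paste0("outlier", seq_len(ncol(out)))
      X <- cbind(X, out)
    }
  }
  box <- run_boxcar(task, run_index, run_start_s, n, tr_s)
  if (any(box != 0)) {
    h <- hrf_double_gamma(tr_s)
    reg <- stats::convolve(c(box, numeric(length(h))), rev(h),
                           type = "open")[seq_len(n)]
    task_cols <- cbind(task_hrf = reg, d_task_hrf = drop(temporal_derivative(reg)))
    X <- cbind(X, task_cols)
  }
  X
}

# OLS residuals of Y (t x v) on X, dropping collinear columns via pivoted QR.
ols_residuals <- function(X, Y, warn_label = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("%s rank-deficient; dropping collinear columns: %s",
                    warn_label, paste(dropped, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y - X %*% qr.coef(qrX, Y)
}

#' Regress confounds and trial-evoked signal out of a timeseries
#'
#' Per-run ordinary least squares of every voxel on an intercept, the six
#' motion parameters, white-matter/CSF/global signals (each plus its backward
#' temporal derivative), outlier stick regressors, and the task boxcar
#' convolved with the double-gamma HRF plus its derivative. Residuals replace
#' the voxel timeseries; they are orthogonal to every regressor within a run.
#'
#' @param ts A [bold_timeseries()].
#' @param conf A [confound_set()] aligned to `ts`.
#' @param task A [task_design()] (may contain no events for baseline runs).
#' @return A `bold_ts` of residuals with the same run structure.
#' @export
confound_regress <- function(ts, conf, task) {
  nt <- n_timepoints(ts)
  if (nrow(conf$motion6) != nt)
    stop("confound rows do not match timeseries length")
  d <- dim(ts$values)
  Y <- matrix(ts$values, nrow = prod(d[1:3]), ncol = d[4])
  out <- Y
  for (ri in seq_along(ts$run_slices)) {
    sl <- ts$run_slices[[ri]]
    rows <- sl[1]:sl[2]
    run_start_s <- (sl[1] - 1) * ts$tr_s
    X <- build_design(conf, task, ri, rows, run_start_s, ts$tr_s)
    out[, rows] <- t(ols_residuals(X, t(Y[, rows, drop = FALSE]),
                                   warn_label = sprintf("run %d design", ri)))
  }
  ts$values <- array(out, dim = d)
  ts
}

# ---- zero-phase Butterworth filtering -------------------------------------

# Steady-state initial filter state (direct form II transposed) per unit of
# input amplitude, so that step inputs produce no start-up transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  # companion matrix of a
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  drop(solve(diag(n - 1) - t(A), B))
}

# IIR filter along the time axis (columns) of x (voxels x time), direct form
# II transposed in compiled code. zi_unit scales with the first column of x.
lfilter_mat <- function(b, a, x, zi_unit) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  cpp_iir_time(b, a, x, zi_unit)
}

# Forward-backward filtering along time (x: voxels x time) with
# odd-reflection padding (zero phase).
filtfilt_mat <- function(b, a, x) {
  n <- max(length(a), length(b))
  padlen <- 3 * (n - 1)
  nt <- ncol(x)
  if (nt <= padlen)
    stop(sprintf("run of %d samples too short for filter warm-up (%d)",
                 nt, padlen + 1))
  zi <- lfilter_zi(b, a)
  pre <- 2 * x[, rep(1, padlen), drop = FALSE] -
    x[, (padlen + 1):2, drop = FALSE]
  post <- 2 * x[, rep(nt, padlen), drop = FALSE] -
    x[, (nt - 1):(nt - padlen), drop = FALSE]
  ext <- cbind(pre, x, post)
  y <- lfilter_mat(b, a, ext, zi)
  y <- lfilter_mat(b, a, y[, ncol(y):1, drop = FALSE], zi)
  y <- y[, ncol(y):1, drop = FALSE]
  y[, (padlen + 1):(padlen + nt), drop = FALSE]
}

butter_band <- function(low_hz, high_hz, fs, order = 4) {
  nyq <- fs / 2
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency")
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  list(b = flt$b, a = flt$a)
}

#' Bandpass-filter a timeseries per run
#'
#' Zero-phase (forward-backward) 4th-order Butterworth bandpass applied
#' independently within each run. The passband floor removes low-frequency
#' drift (subsuming a preliminary 0.01-Hz high-pass) and the ceiling excludes
#' the stimulus presentation frequency (1 image / 6 s = 0.17 Hz).
#'
#' @param ts A [bold_timeseries()].
#' @param low_hz,high_hz Passband edges in Hz.
#' @return Filtered `bold_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  flt <- butter_band(low_hz, high_hz, fs = 1 / ts$tr_s)
  d <- dim(ts$values)
  Y <- matrix(ts$values, nrow = prod(d[1:3]), ncol = d[4])
  for (ri in seq_along(ts$run_slices)) {
    sl <- ts$run_slices[[ri]]
    rows <- sl[1]:sl[2]
    Y[, rows] <- tryCatch(
      filtfilt_mat(flt$b, flt$a, Y[, rows, drop = FALSE]),
      error = function(e) stop(sprintf("bandpass failed in run %d: %s",
                                       ri, conditionMessage(e))))
  }
  ts$values <- array(Y, dim = d)
  ts
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing of every volume to the requested full width
#' at half maximum. Kernel weights are renormalized at grid edges, so a
#' spatially constant volume passes through unchanged. `fwhm_mm = 0` is the
#' identity.
#'
#' @param ts A [bold_timeseries()] (or a 3D array via `gaussian_smooth_vol`).
#' @param fwhm_mm Target smoothness, mm FWHM.
#' @return Smoothed `bold_ts`.
#' @export
gaussian_smooth <- function(ts, fwhm_mm = 6) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(ts)
  d <- dim(ts$values)
  sigma_vox <- rep(fwhm_mm / (2 * sqrt(2 * log(2))) / ts$voxel_mm, 3)
  sm <- cpp_gaussian_smooth(as.numeric(ts$values), d[1:3], d[4], sigma_vox)
  ts$values <- array(sm, dim = d)
  ts
}

#' @rdname gaussian_smooth
#' @param vol 3D numeric array.
#' @param voxel_mm Voxel edge length in mm.
#' @export
gaussian_smooth_vol <- function(vol, fwhm_mm = 6, voxel_mm = 2) {
  stopifnot(fwhm_mm >= 0, length(dim(vol)) == 3L)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- rep(fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm, 3)
  array(cpp_gaussian_smooth(as.numeric(vol), dim(vol), 1L, sigma_vox),
        dim = dim(vol))
}

# ---- motion quality control -----------------------------------------------

#' Framewise displacement from rigid-body motion parameters
#'
#' Per-frame sum of absolute frame-to-frame translation changes plus
#' `radius_mm` times absolute rotation changes (rotations in radians mapped
#' to arc length on a sphere of the given radius). The first frame of each
#' run has FD 0.
#'
#' @param motion6 t x 6 matrix (translations mm, rotations rad).
#' @param radius_mm Head radius used to convert rotations to mm.
#' @return Numeric vector of per-frame displacements.
#' @export
framewise_displacement <- function(motion6, radius_mm = 50) {
  motion6 <- as.matrix(motion6)
  stopifnot(ncol(motion6) == 6L)
  d <- abs(apply(motion6, 2, function(col) c(0, diff(col))))
  d <- matrix(d, ncol = 6)
  rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Exclude high-motion runs
#'
#' Computes mean framewise displacement per run and drops runs exceeding the
#' a-priori threshold.
#'
#' @param ts A [bold_timeseries()].
#' @param conf A [confound_set()].
#' @param threshold_mm Mean-FD exclusion threshold (mm).
#' @param radius_mm Rotation radius for [framewise_displacement()].
#' @return List with `retained` (run indices), `mean_fd` (per run) and
#'   `excluded`.
#' @export
qc_exclude_runs <- function(ts, conf, threshold_mm = 1.5, radius_mm = 50) {
  mean_fd <- vapply(ts$run_slices, function(sl) {
    rows <- sl[1]:sl[2]
    mean(framewise_displacement(conf$motion6[rows, , drop = FALSE],
                                radius_mm = radius_mm))
  }, numeric(1))
  retained <- which(mean_fd <= threshold_mm)
  excluded <- setdiff(seq_along(ts$run_slices), retained)
  if (length(retained) == 0) stop("all runs excluded by motion QC")
  if (length(excluded) > 0)
    message(sprintf("motion QC excluded run(s) %s (mean FD %s mm)",
                    paste(excluded, collapse = ", "),
                    paste(sprintf("%.2f", mean_fd[excluded]), collapse = ", ")))
  list(retained = retained, mean_fd = mean_fd, excluded = excluded)
}
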