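# Epoching and seed-to-voxel Fisher-z connectivity maps.

#' Concatenate runs into analysis epochs
#'
#' @param ts A preprocessed [bold_timeseries()].
#' @param spec An [epoch_spec()].
#' @param retained_runs Run indices surviving QC (default all).
#' @return Named list of voxel-by-time matrices, one per available epoch.
#'   Epochs whose runs were excluded are omitted with a message.
#' @export
epoch_segments <- function(ts, spec = epoch_spec(),
                           retained_runs = seq_along(ts$run_slices)) {
  d <- dim(ts$values)
  Y <- matrix(ts$values, nrow = prod(d[1:3]), ncol = d[4])
  out <- list()
  for (ep in names(spec$mapping)) {
    runs <- spec$mapping[[ep]]
    if (any(runs > length(ts$run_slices)) || !all(runs %in% retained_runs)) {
      message(sprintf("epoch '%s' unavailable (missing or excluded run)", ep))
      next
    }
    cols <- unlist(lapply(runs, function(r) {
      sl <- ts$run_slices[[r]]
      sl[1]:sl[2]
    }))
    out[[ep]] <- Y[, cols, drop = FALSE]
  }
  attr(out, "grid_dims") <- d[1:3]
  out
}

#' Seed-to-voxel connectivity map
#'
#' Correlates the mean seed-ROI timeseries with every voxel and Fisher
#' z-transforms the result, clipping |r| at `1 - 1e-7` so the map is finite.
#' Zero-variance voxels get z = 0 (their count is reported via a message).
#'
#' @param segment Voxel-by-time matrix (an element of [epoch_segments()])
#'   with a `grid_dims` attribute, or with `grid_dims` supplied.
#' @param roi A [roi_mask()] on the same grid.
#' @param grid_dims Grid dimensions if not attached to `segment`.
#' @return 3D array of Fisher z values (class `seed_map` attributes: seed
#'   label).
#' @export
seed_map <- function(segment, roi, grid_dims = attr(segment, "grid_dims")) {
  if (is.null(grid_dims)) grid_dims <- dim(roi$mask)
  stopifnot(nrow(segment) == prod(grid_dims),
            all(dim(roi$mask) == grid_dims))
  if (ncol(segment) < 8) stop("segment must have at least 8 samples")
  seed_ts <- colMeans(segment[as.vector(roi$mask), , drop = FALSE])
  if (sd(seed_ts) == 0) stop("seed timeseries has zero variance")
  vx <- segment - rowMeans(segment)
  sx <- sqrt(rowSums(vx^2))
  sy <- seed_ts - mean(seed_ts)
  r <- as.vector(vx %*% sy) / (sx * sqrt(sum(sy^2)))
  n_bad <- sum(sx == 0)
  if (n_bad > 0) {
    message(sprintf("%d zero-variance voxel(s) set to z = 0", n_bad))
    r[sx == 0] <- 0
  }
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  out <- array(z, dim = grid_dims)
  attr(out, "seed") <- roi$label
  class(out) <- c("seed_map", class(out))
  out
}

#' Epoch-minus-baseline differential connectivity map
#'
#' @param epoch_map,baseline_map 3D Fisher-z arrays on the same grid.
#' @return 3D array of voxelwise differences.
#' @export
differential_map <- function(epoch_map, baseline_map) {
  if (!all(dim(epoch_map) == dim(baseline_map)))
    stop("grid mismatch between epoch and baseline maps")
  out <- unclass(epoch_map) - unclass(baseline_map)
  attr(out, "seed") <- attr(epoch_map, "seed")
  out
}

#' Full background-connectivity stage for one participant/condition
#'
#' Runs the canonical order: confound + task-evoked regression, spatial
#' smoothing, per-run bandpass, epoch concatenation, seed maps per epoch and
#' epoch-minus-baseline differentials.
#'
#' @param ts A [bold_timeseries()].
#' @param conf A [confound_set()].
#' @param task A [task_design()].
#' @param roi A [roi_mask()] seed.
#' @param spec An [epoch_spec()].
#' @param fwhm_mm Smoothing FWHM (mm); 0 disables.
#' @param band Passband in Hz.
#' @param qc Apply motion-based run exclusion first.
#' @return List with `epoch_maps` (named list of 3D z maps including
#'   baseline) and `diff_maps` (epoch minus baseline, image epochs only).
#' @export
background_connectivity_maps <- function(ts, conf, task, roi,
                                         spec = epoch_spec(), fwhm_mm = 6,
                                         band = c(0.01, 0.1), qc = TRUE) {
  retained <- seq_along(ts$run_slices)
  if (qc) retained <- qc_exclude_runs(ts, conf)$retained
  ts <- confound_regress(ts, conf, task)
  ts <- gaussian_smooth(ts, fwhm_mm)
  ts <- bandpass(ts, band[1], band[2])
  segs <- epoch_segments(ts, spec, retained_runs = retained)
  if (!("baseline" %in% names(segs)))
    stop("baseline epoch unavailable; cannot form differentials")
  maps <- lapply(segs, seed_map, roi = roi)
  diffs <- lapply(setdiff(names(maps), "baseline"), function(ep)
    differential_map(maps[[ep]], maps$baseline))
  names(diffs) <- setdiff(names(maps), "baseline")
  list(epoch_maps = maps, diff_maps = diffs)
}
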