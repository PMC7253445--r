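# Lightweight S3 containers for the connectivity pipeline. Voxel indices are
# 1-based in R code; world coordinates (mm) appear only at NIfTI I/O via the
# affine.

#' BOLD timeseries with run structure
#'
#' Wraps a 4D numeric array `(x, y, z, t)` together with its repetition time
#' and run boundaries. All downstream preprocessing (confound regression,
#' filtering, epoching) operates per run.
#'
#' @param values 4D numeric array, time in the last dimension.
#' @param tr_s Repetition time in seconds (positive).
#' @param run_slices List of integer pairs `c(start, end)` (1-based, inclusive)
#'   that are disjoint, ordered and cover the time axis exactly.
#' @param condition Condition label, e.g. `"Stressor"` or `"Neutral"`.
#' @param participant_id Participant identifier.
#' @param voxel_mm Voxel edge length in mm (isotropic grid).
#' @return An object of class `bold_ts`.
#' @export
bold_timeseries <- function(values, tr_s, run_slices,
                            condition = NA_character_,
                            participant_id = NA_character_,
                            voxel_mm = 2) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive")
  if (any(!is.finite(values))) stop("timeseries values must be finite")
  nt <- dim(values)[4]
  run_slices <- lapply(run_slices, as.integer)
  starts <- vapply(run_slices, `[`, integer(1), 1L)
  ends <- vapply(run_slices, `[`, integer(1), 2L)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts > ends) ||
      starts[1] != 1L || ends[length(ends)] != nt ||
      (length(starts) > 1 && any(starts[-1] != ends[-length(ends)] + 1L))) {
    stop("run_slices must be disjoint, ordered and cover the time axis")
  }
  structure(
    list(values = values, tr_s = tr_s, run_slices = run_slices,
         condition = condition, participant_id = participant_id,
         voxel_mm = voxel_mm),
    class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bold_ts> %dx%dx%d voxels, %d samples (TR %.3g s), %d runs, %s/%s\n",
              d[1], d[2], d[3], d[4], x$tr_s, length(x$run_slices),
              x$participant_id, x$condition))
  invisible(x)
}

n_timepoints <- function(ts) dim(ts$values)[4]

#' Confound table aligned to a BOLD timeseries
#'
#' @param motion6 t x 6 matrix of rigid-body motion parameters
#'   (3 translations in mm, 3 rotations in radians).
#' @param wm,csf,global Length-t nuisance signal vectors (white matter,
#'   cerebrospinal fluid, global mean).
#' @param outliers t x k binary matrix of stick regressors for nonlinear
#'   motion outliers (each column one-hot in time), or `NULL`.
#' @return An object of class `confound_set`.
#' @export
confound_set <- function(motion6, wm, csf, global, outliers = NULL) {
  motion6 <- as.matrix(motion6)
  stopifnot(ncol(motion6) == 6L)
  t_len <- nrow(motion6)
  stopifnot(length(wm) == t_len, length(csf) == t_len, length(global) == t_len)
  if (!is.null(outliers)) {
    outliers <- as.matrix(outliers)
    stopifnot(nrow(outliers) == t_len)
    if (any(colSums(outliers != 0) > 1))
      stop("outlier indicator columns must be one-hot in time")
  }
  structure(list(motion6 = motion6, wm = as.numeric(wm), csf = as.numeric(csf),
                 global = as.numeric(global), outliers = outliers),
            class = "confound_set")
}

#' Task event design
#'
#' Image-presentation events used to model (and regress out) trial-evoked
#' responses. The default block structure is 5-s images alternating with 1-s
#' inter-stimulus intervals inside 66-s runs.
#'
#' @param events data.frame with columns `onset_s`, `duration_s`, `run`
#'   (1-based run index). Onsets are seconds from the start of the session.
#' @param run_duration_s Run duration in seconds.
#' @param image_duration_s,isi_s Stimulus and inter-stimulus durations.
#' @return An object of class `task_design`.
#' @export
task_design <- function(events, run_duration_s = 66,
                        image_duration_s = 5, isi_s = 1) {
  stopifnot(is.data.frame(events),
            all(c("onset_s", "duration_s", "run") %in% names(events)))
  if (is.unsorted(events$onset_s)) stop("event onsets must be non-decreasing")
  structure(list(events = events, run_duration_s = run_duration_s,
                 image_duration_s = image_duration_s, isi_s = isi_s),
            class = "task_design")
}

#' Standard image-run task design
#'
#' Builds the canonical block design: `n_baseline_runs` runs with no events
#' followed by `n_image_runs` runs of images (5 s on, 1 s off).
#'
#' @param n_baseline_runs,n_image_runs Run counts.
#' @param run_len_s Run length in seconds.
#' @param image_duration_s,isi_s Stimulus and inter-stimulus durations.
#' @return A [task_design()].
#' @export
default_task_design <- function(n_baseline_runs = 2, n_image_runs = 6,
                                run_len_s = 66, image_duration_s = 5,
                                isi_s = 1) {
  per <- image_duration_s + isi_s
  n_img <- floor(run_len_s / per)
  ev <- do.call(rbind, lapply(seq_len(n_image_runs), function(r) {
    run0 <- (n_baseline_runs + r - 1) * run_len_s
    data.frame(onset_s = run0 + (seq_len(n_img) - 1) * per,
               duration_s = image_duration_s,
               run = n_baseline_runs + r)
  }))
  if (is.null(ev)) ev <- data.frame(onset_s = numeric(0),
                                    duration_s = numeric(0), run = integer(0))
  task_design(ev, run_duration_s = run_len_s,
              image_duration_s = image_duration_s, isi_s = isi_s)
}

#' Region-of-interest mask
#'
#' @param mask 3D logical/0-1 array on the analysis grid.
#' @param label One of `"full_hipp"`, `"aHPC"`, `"pHPC"`, `"control_sphere"`,
#'   `"custom"` or any free label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "custom") {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("ROI mask must contain at least one voxel")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s', %d voxels on %s grid\n", x$label,
              sum(x$mask), paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Epoch specification
#'
#' Maps runs onto the analysis epochs. The default follows the two-runs-per-
#' epoch convention: baseline = runs 1-2, early = image runs 1-2 (runs 3-4),
#' mid = runs 5-6, late = runs 7-8; each epoch spans 132 s at 66-s runs.
#'
#' @param mapping Named list of integer run-index pairs.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(mapping = list(baseline = c(1L, 2L), early = c(3L, 4L),
                                      mid = c(5L, 6L), late = c(7L, 8L))) {
  runs <- unlist(mapping)
  if (anyDuplicated(runs)) stop("epochs must use disjoint runs")
  for (m in mapping) {
    if (length(m) != 2L || m[2] != m[1] + 1L)
      stop("each epoch must be exactly two consecutive runs")
  }
  structure(list(mapping = lapply(mapping, as.integer)), class = "epoch_spec")
}

#' Epoch duration implied by an epoch specification
#'
#' @param spec An [epoch_spec()].
#' @param run_len_s Run length in seconds.
#' @return Duration in seconds of each (two-run) epoch.
#' @export
epoch_duration_s <- function(spec = epoch_spec(), run_len_s = 66) {
  lens <- vapply(spec$mapping, length, integer(1))
  unname(lens[1] * run_len_s)
}
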