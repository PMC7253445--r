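# Format round-tripping: NIfTI volumes and label images, BIDS-style TSV
# tables, JSON/YAML configs and results.

#' Write / read a NIfTI volume
#'
#' @param arr 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size recorded in the header.
#' @return `write_nifti_vol` returns `path` invisibly; `read_nifti_vol`
#'   returns a plain array with `voxel_mm` attribute.
#' @export
write_nifti_vol <- function(arr, path, voxel_mm = 2) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), rep(1, nd - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_vol
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[1]
  attr(out, "affine") <- structure(RNifti::xform(img), code = NULL)
  out
}

#' Write / read an ROI mask as NIfTI
#'
#' @param roi A [roi_mask()].
#' @param path NIfTI path.
#' @param voxel_mm Voxel size.
#' @param label Label for the re-read mask.
#' @export
write_roi_mask <- function(roi, path, voxel_mm = 2) {
  write_nifti_vol(array(as.integer(roi$mask), dim = dim(roi$mask)), path,
                  voxel_mm)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path, label = "custom") {
  arr <- read_nifti_vol(path)
  roi_mask(arr != 0, label)
}

#' Write / read a feature matrix as TSV
#'
#' Rows are participants (first column `participant`), remaining columns are
#' cluster ids.
#'
#' @param features Numeric matrix with participant rownames.
#' @param path TSV path.
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(participant = rownames(features), features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$participant
  m
}

#' Write / read confounds as BIDS-style TSV
#'
#' Columns: `trans_x/y/z`, `rot_x/y/z`, `wm`, `csf`, `global`,
#' `outlier_1..k`.
#'
#' @param conf A [confound_set()].
#' @param path TSV path.
#' @export
write_confounds_tsv <- function(conf, path) {
  df <- data.frame(conf$motion6)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  df$wm <- conf$wm
  df$csf <- conf$csf
  df$global <- conf$global
  if (!is.null(conf$outliers)) {
    o <- as.data.frame(conf$outliers)
    names(o) <- paste0("outlier_", seq_len(ncol(o)))
    df <- cbind(df, o)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confounds_tsv
#' @export
read_confounds_tsv <- function(path) {
  df <- read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "wm", "csf", "global")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("malformed confounds TSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out_cols <- grep("^outlier_", names(df), value = TRUE)
  confound_set(as.matrix(df[, need[1:6]]), df$wm, df$csf, df$global,
               if (length(out_cols)) as.matrix(df[, out_cols, drop = FALSE]))
}

#' Write / read task events as BIDS-style TSV
#'
#' Columns: `onset`, `duration`, `run`, `condition`.
#'
#' @param task A [task_design()].
#' @param path TSV path.
#' @param condition Condition label recorded per event.
#' @export
write_events_tsv <- function(task, path, condition = "Stressor") {
  df <- data.frame(onset = task$events$onset_s,
                   duration = task$events$duration_s,
                   run = task$events$run, condition = condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param run_duration_s,image_duration_s,isi_s Design constants.
#' @export
read_events_tsv <- function(path, run_duration_s = 66, image_duration_s = 5,
                            isi_s = 1) {
  df <- read.delim(path)
  need <- c("onset", "duration", "run")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("malformed events TSV, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  task_design(data.frame(onset_s = df$onset, duration_s = df$duration,
                         run = df$run),
              run_duration_s = run_duration_s,
              image_duration_s = image_duration_s, isi_s = isi_s)
}

#' Serialize / deserialize a cluster set
#'
#' Writes a NIfTI label image (voxel value = cluster id) plus a JSON sidecar
#' with id, sign, size and peak coordinate per cluster.
#'
#' @param clusters A [clusterize()] result.
#' @param nii_path,json_path Output paths.
#' @param voxel_mm Voxel size.
#' @export
write_cluster_set <- function(clusters, nii_path, json_path, voxel_mm = 2) {
  lab <- array(0L, dim = clusters$grid_dims)
  for (cl in clusters$clusters) lab[cl$lin_idx] <- cl$id
  write_nifti_vol(lab, nii_path, voxel_mm)
  meta <- lapply(clusters$clusters, function(cl)
    list(id = cl$id, sign = cl$sign, size = cl$size,
         peak = as.integer(cl$peak)))
  jsonlite::write_json(list(voxel_p = clusters$voxel_p, clusters = meta),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' @rdname write_cluster_set
#' @export
read_cluster_set <- function(nii_path, json_path) {
  lab <- read_nifti_vol(nii_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dims <- dim(lab)
  clusters <- lapply(seq_len(nrow(meta$clusters)), function(i) {
    id <- meta$clusters$id[i]
    idx <- which(lab == id)
    list(id = id, voxels = arrayInd(idx, dims), lin_idx = idx,
         sign = meta$clusters$sign[i], size = meta$clusters$size[i],
         peak = unlist(meta$clusters$peak[i]))
  })
  structure(list(clusters = clusters, grid_dims = dims,
                 voxel_p = meta$voxel_p), class = "cluster_set")
}

#' Write an sCPM result as JSON (plus the null distribution as TSV)
#'
#' @param result An [scpm_fit()] result.
#' @param json_path Output JSON path.
#' @param null_tsv_path Optional path for the permutation null (one column
#'   per network).
#' @export
write_scpm_result_json <- function(result, json_path, null_tsv_path = NULL) {
  payload <- list(
    scheme = result$scheme, p_thresh = result$p_thresh, seed = result$seed,
    n_perm = result$n_perm, r_s = as.list(result$r_s),
    p_value = if (!is.null(result$p_value)) as.list(result$p_value),
    observed = unname(result$observed),
    predicted = list(pos = unname(result$predicted[, "pos"]),
                     neg = unname(result$predicted[, "neg"]),
                     combined = unname(result$predicted[, "combined"])),
    everyfold = result$everyfold,
    folds = lapply(result$folds, function(f)
      list(held_out = f$held_out, pos_ids = f$pos_ids, neg_ids = f$neg_ids,
           fallback = f$fallback)))
  if (!is.null(null_tsv_path) && !is.null(result$null_rs)) {
    write.table(as.data.frame(result$null_rs), null_tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    payload$null_path <- null_tsv_path
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(json_path)
}

#' Write a synthetic study to disk in the pipeline layout
#'
#' Produces `ratings.tsv`, `masks/seed.nii.gz`, per-cluster truth masks, a
#' JSON config snapshot and, per participant/condition,
#' `<sub>/<condition>_bold.nii.gz`, `_confounds.tsv` and `_events.tsv`.
#'
#' @param study A [generate_study_dataset()] result.
#' @param dir Output directory (created).
#' @return `dir` invisibly.
#' @export
write_sim_dataset <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  vx <- study$config$voxel_mm
  write.table(study$ratings, file.path(dir, "ratings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_roi_mask(study$seed_mask, file.path(dir, "masks", "seed.nii.gz"), vx)
  for (i in seq_along(study$cluster_masks))
    write_roi_mask(study$cluster_masks[[i]],
                   file.path(dir, "masks", sprintf("truth%d.nii.gz", i)), vx)
  cfg <- study$config
  cfg$seed_roi <- NULL
  cfg$target_clusters <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (pid in names(study$acquisitions)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (cond in names(study$acquisitions[[pid]])) {
      acq <- study$acquisitions[[pid]][[cond]]
      write_nifti_vol(acq$ts$values,
                      file.path(pdir, paste0(cond, "_bold.nii.gz")), vx)
      write_confounds_tsv(acq$confounds,
                          file.path(pdir, paste0(cond, "_confounds.tsv")))
      write_events_tsv(acq$task, file.path(pdir, paste0(cond, "_events.tsv")),
                       condition = cond)
    }
  }
  invisible(dir)
}
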