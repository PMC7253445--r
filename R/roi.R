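# ROI geometry: longitudinal-axis splits and spherical control seeds.

#' Split an ROI into anterior and posterior thirds
#'
#' Projects mask voxels onto the longitudinal axis and keeps the
#' anterior-most and posterior-most thirds of the projected extent. The axis
#' is either the first principal axis of the voxel cloud (`axis = "principal"`)
#' or the grid's anterior-posterior axis (`axis = "grid"`, the second array
#' dimension, increasing anteriorly). With the principal axis, the sign is
#' oriented so that it correlates positively with the grid's anterior
#' direction.
#'
#' @param roi A [roi_mask()] spanning at least 3 distinct positions along the
#'   chosen axis.
#' @param axis `"principal"` or `"grid"`.
#' @return List with elements `anterior` and `posterior` ([roi_mask()]s,
#'   disjoint subsets of the input).
#' @export
split_longitudinal_thirds <- function(roi, axis = c("principal", "grid")) {
  axis <- match.arg(axis)
  vox <- which(roi$mask, arr.ind = TRUE)
  if (axis == "grid") {
    proj <- vox[, 2]
  } else {
    ctr <- scale(vox, center = TRUE, scale = FALSE)
    pc1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
    if (pc1[2] < 0 || (pc1[2] == 0 && sum(pc1) < 0)) pc1 <- -pc1
    proj <- drop(ctr %*% pc1)
  }
  lo <- min(proj)
  hi <- max(proj)
  if (length(unique(proj)) < 3 || hi - lo <= 0)
    stop("ROI extent along the longitudinal axis is degenerate")
  third <- (hi - lo) / 3
  ant <- proj >= hi - third
  post <- proj <= lo + third
  mk <- function(sel, label) {
    m <- array(FALSE, dim = dim(roi$mask))
    m[vox[sel, , drop = FALSE]] <- TRUE
    roi_mask(m, label)
  }
  list(anterior = mk(ant, "aHPC"), posterior = mk(post, "pHPC"))
}

#' Spherical ROI on a voxel grid
#'
#' Selects voxels whose centers lie within `radius_mm` of a point, using the
#' grid's isotropic voxel size. Coordinates are in mm with voxel `(1,1,1)`
#' centered at the origin.
#'
#' @param center_mm Length-3 numeric center in mm.
#' @param radius_mm Sphere radius in mm.
#' @param grid_dims Length-3 integer grid dimensions.
#' @param voxel_mm Voxel edge length in mm.
#' @param label ROI label.
#' @return A [roi_mask()].
#' @export
sphere_roi <- function(center_mm, radius_mm = 7, grid_dims, voxel_mm = 2,
                       label = "control_sphere") {
  stopifnot(length(center_mm) == 3L, length(grid_dims) == 3L, radius_mm >= 0)
  ax <- lapply(1:3, function(a) ((seq_len(grid_dims[a]) - 1) * voxel_mm -
                                   center_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  m <- d2 <= radius_mm^2
  if (!any(m)) stop("sphere contains no voxel centers")
  roi_mask(m, label)
}
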