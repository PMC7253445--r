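# Group-level definition of stressor-modulated clusters from participants'
# differential connectivity maps, with permutation cluster-extent correction.

# Stack a list of 3D arrays into participants x voxels.
stack_maps <- function(maps) {
  dims <- dim(maps[[1]])
  mat <- t(vapply(maps, function(m) {
    if (!all(dim(m) == dims)) stop("grid mismatch across participant maps")
    as.numeric(m)
  }, numeric(prod(dims))))
  attr(mat, "grid_dims") <- dims
  mat
}

# Per-participant condition-difference map: mean over epochs of the stressor
# differentials minus mean over epochs of the neutral differentials.
condition_difference_map <- function(participant) {
  s <- Reduce(`+`, participant$Stressor) / length(participant$Stressor)
  n <- Reduce(`+`, participant$Neutral) / length(participant$Neutral)
  s - n
}

#' Group contrast of stressor- vs. neutral-condition connectivity
#'
#' For each participant the condition difference of epoch-minus-baseline
#' differential maps is averaged over epochs; the resulting per-participant
#' difference maps are tested against zero voxelwise with a one-sample t test.
#' Optional covariates (e.g. sex) are regressed out of the difference maps
#' before testing, with degrees of freedom reduced accordingly.
#'
#' @param diff_maps Either a named list per participant of
#'   `list(Stressor = <list of epoch 3D maps>, Neutral = ...)`, or a
#'   participants x voxels matrix of precomputed condition differences with a
#'   `grid_dims` attribute.
#' @param covariates Optional numeric matrix (participants x q).
#' @return Object of class `group_stat_map`: list with 3D `stat` and `p`
#'   arrays, `n_participants` and the contrast label.
#' @export
group_contrast <- function(diff_maps, covariates = NULL) {
  if (is.list(diff_maps)) {
    has_both <- vapply(diff_maps, function(p)
      all(c("Stressor", "Neutral") %in% names(p)) &&
        length(p$Stressor) > 0 && length(p$Neutral) > 0, logical(1))
    if (any(!has_both)) {
      message(sprintf("dropping %d participant(s) missing a condition",
                      sum(!has_both)))
      diff_maps <- diff_maps[has_both]
      if (!is.null(covariates))
        covariates <- covariates[has_both, , drop = FALSE]
    }
    D <- stack_maps(lapply(diff_maps, condition_difference_map))
  } else {
    D <- diff_maps
  }
  dims <- attr(D, "grid_dims")
  n <- nrow(D)
  if (n < 4) stop("group contrast needs at least 4 participants")
  df <- n - 1
  if (!is.null(covariates)) {
    # centered covariates: residualizing leaves the group mean untouched
    X <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
    qx <- qr(X)
    D <- D - qr.fitted(qx, D)
    df <- n - 1 - qx$rank
  }
  mu <- colMeans(D)
  ss <- colSums(D^2) - n * mu^2
  se <- sqrt(ss / df / n)
  tstat <- ifelse(se > 0, mu / se, 0)
  p <- 2 * pt(-abs(tstat), df = df)
  structure(list(stat = array(tstat, dims), p = array(p, dims),
                 n_participants = n, df = df,
                 contrast = "Stressor vs Neutral"),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("<group_stat_map> %s, n = %d, grid %s\n", x$contrast,
              x$n_participants, paste(dim(x$stat), collapse = "x")))
  invisible(x)
}

#' Bi-sided first-nearest-neighbour clustering of a thresholded stat map
#'
#' Voxels with `p < voxel_p` are grouped into connected components under face
#' (NN1) adjacency, separately for positive and negative statistics (bi-sided:
#' opposite signs never merge even when touching). Cluster ids are assigned
#' deterministically by descending size, ties broken by lexicographically
#' smallest peak coordinate.
#'
#' @param stat_map A `group_stat_map` (from [group_contrast()]).
#' @param voxel_p Voxelwise threshold in (0, 1).
#' @param min_size Minimum cluster extent (voxels) to keep.
#' @return Object of class `cluster_set`: list of clusters
#'   (`id`, `voxels` (index matrix), `sign`, `size`, `peak`), plus grid dims.
#' @export
clusterize <- function(stat_map, voxel_p = 0.001, min_size = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1)
  dims <- dim(stat_map$stat)
  supra <- stat_map$p < voxel_p
  clusters <- list()
  for (sgn in c(1, -1)) {
    m <- supra & (sign(stat_map$stat) == sgn)
    if (!any(m)) next
    lab <- cpp_label_components(as.logical(m), dims)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      if (length(idx) < min_size) next
      stats_here <- abs(as.numeric(stat_map$stat)[idx])
      peak_idx <- idx[which.max(stats_here)]
      clusters[[length(clusters) + 1]] <- list(
        voxels = arrayInd(idx, dims), lin_idx = idx, sign = sgn,
        size = length(idx),
        peak = drop(arrayInd(peak_idx, dims)))
    }
  }
  if (length(clusters) > 0) {
    peaks <- t(vapply(clusters, `[[`, numeric(3), "peak"))
    sizes <- vapply(clusters, `[[`, numeric(1), "size")
    ord <- order(-sizes, peaks[, 1], peaks[, 2], peaks[, 3])
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) clusters[[i]]$id <- i
  }
  structure(list(clusters = clusters, grid_dims = dims,
                 voxel_p = voxel_p), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) on %s grid (voxel p < %g)\n",
              length(x$clusters), paste(x$grid_dims, collapse = "x"),
              x$voxel_p))
  invisible(x)
}

#' Permutation cluster-extent threshold
#'
#' Family-wise cluster-size correction by sign-flip permutation: for each
#' permutation the participant condition-difference maps are randomly
#' sign-flipped, the voxelwise one-sample t map recomputed and thresholded at
#' `voxel_p`, and the maximum bi-sided NN1 cluster size recorded. The
#' returned extent `k` is the smallest integer for which the null probability
#' of observing any cluster of size >= k is at most `alpha`.
#'
#' @param diff_maps Participants x voxels matrix of condition differences
#'   (with `grid_dims` attribute) or the list form accepted by
#'   [group_contrast()].
#' @param voxel_p Voxelwise threshold.
#' @param alpha Family-wise error rate.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `k` (minimum significant size), `max_sizes` (null
#'   max-cluster sizes) and the settings used.
#' @export
cluster_extent_threshold <- function(diff_maps, voxel_p = 0.001, alpha = 0.05,
                                     n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.list(diff_maps) && !is.matrix(diff_maps))
    diff_maps <- stack_maps(lapply(diff_maps, condition_difference_map))
  dims <- attr(diff_maps, "grid_dims")
  n <- nrow(diff_maps)
  df <- n - 1
  tcrit <- qt(1 - voxel_p / 2, df)
  set.seed(seed)
  max_sizes <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    Dp <- diff_maps * flips
    mu <- colMeans(Dp)
    se <- sqrt((colSums(Dp^2) - n * mu^2) / (df * n))
    tstat <- ifelse(se > 0, mu / se, 0)
    mx <- 0L
    for (sgn in c(1, -1)) {
      m <- (sgn * tstat) > tcrit
      if (!any(m)) next
      lab <- cpp_label_components(m, dims)
      if (max(lab) > 0) mx <- max(mx, max(tabulate(lab[lab > 0L])))
    }
    max_sizes[b] <- mx
  }
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(k = k, max_sizes = max_sizes, voxel_p = voxel_p, alpha = alpha,
       n_perm = n_perm, seed = seed)
}

#' Cluster-mean relative connectivity features
#'
#' Builds the sCPM feature matrix: one row per participant, one column per
#' cluster, each entry the mean over cluster voxels of the chosen relative
#' differential — stressor epoch minus baseline (`reference = "sb"`) or the
#' condition contrast of differentials (`"sbnb"`) — averaged over the early,
#' mid and late epochs (`window = "all"`) or the early epoch only
#' (`window = "early"`).
#'
#' @param z_maps Named list per participant:
#'   `list(Stressor = list(baseline = 3D, early = ..., mid = ..., late = ...),
#'   Neutral = ...)` of Fisher-z seed maps.
#' @param clusters A [clusterize()] result on the same grid.
#' @param reference `"sb"` or `"sbnb"`.
#' @param window `"all"` or `"early"`.
#' @return Numeric matrix participants x clusters with cluster ids as column
#'   names and provenance attributes.
#' @export
cluster_mean_features <- function(z_maps, clusters,
                                  reference = c("sb", "sbnb"),
                                  window = c("all", "early")) {
  reference <- match.arg(reference)
  window <- match.arg(window)
  epochs <- if (window == "all") c("early", "mid", "late") else "early"
  ids <- vapply(clusters$clusters, `[[`, numeric(1), "id")
  dims <- clusters$grid_dims
  feat <- matrix(NA_real_, length(z_maps), length(ids),
                 dimnames = list(names(z_maps), paste0("c", ids)))
  rel_value <- function(cond_maps, lin_idx) {
    vals <- vapply(epochs, function(ep) {
      if (is.null(cond_maps[[ep]])) stop("missing epoch map: ", ep)
      mean(cond_maps[[ep]][lin_idx]) - mean(cond_maps$baseline[lin_idx])
    }, numeric(1))
    mean(vals)
  }
  for (i in seq_along(z_maps)) {
    p <- z_maps[[i]]
    if (!all(dim(p$Stressor$baseline) == dims))
      stop("cluster set and z maps are on different grids")
    for (j in seq_along(ids)) {
      cl <- clusters$clusters[[j]]
      if (any(cl$lin_idx > prod(dims))) stop("cluster outside map bounds")
      v <- rel_value(p$Stressor, cl$lin_idx)
      if (reference == "sbnb") v <- v - rel_value(p$Neutral, cl$lin_idx)
      feat[i, j] <- v
    }
  }
  attr(feat, "reference") <- reference
  attr(feat, "window") <- window
  feat
}
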