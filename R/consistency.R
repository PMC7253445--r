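# Feature-consistency inference across families of sCPM models: every-fold
# cluster sets, linked-shuffle permutation tests, and cross-seed overlap.

#' Clusters selected on every cross-validation fold
#'
#' @param result An [scpm_fit()] result.
#' @return List with `pos` and `neg` cluster-name vectors (intersection over
#'   folds, per network sign).
#' @export
everyfold_clusters <- function(result) {
  stopifnot(inherits(result, "scpm_result"))
  result$everyfold
}

#' Linked-shuffle consistency test across a model family
#'
#' A family is a set of sCPM models sharing the same participants and the
#' same cluster columns (e.g. one seed's clusters entering models for several
#' outcomes, windows and references). The observed statistic per cluster and
#' network sign is the number of models whose every-fold network contains the
#' cluster. Under each permutation, one participant relabeling is applied
#' simultaneously to every outcome in the family (linked shuffle, preserving
#' inter-outcome correlation), all models are re-fit with in-fold selection,
#' and the null model-counts are recorded. P-values use the plus-one
#' estimator on `null count >= observed count`.
#'
#' @param family List of models, each `list(features = matrix, outcome =
#'   vector, label = character)`. All feature matrices must share row and
#'   column sets.
#' @param n_perm Number of linked shuffles.
#' @param seed RNG seed.
#' @param p_thresh In-fold selection threshold.
#' @param scheme,k Cross-validation scheme.
#' @return Object of class `consistency_result`: data.frame `table` with
#'   cluster, sign, observed count and p, plus the null count arrays.
#' @export
consistency_permutation_test <- function(family, n_perm = 1000, seed = 1,
                                         p_thresh = 0.05,
                                         scheme = c("loo", "kfold"), k = 10) {
  scheme <- match.arg(scheme)
  stopifnot(length(family) >= 1)
  n <- nrow(family[[1]]$features)
  p <- ncol(family[[1]]$features)
  cl_names <- colnames(family[[1]]$features)
  if (is.null(cl_names)) cl_names <- paste0("c", seq_len(p))
  for (m in family) {
    if (nrow(m$features) != n || ncol(m$features) != p)
      stop("all models in the family must share participants and clusters")
    if (length(m$outcome) != n) stop("outcome length mismatch in family")
    rn <- rownames(m$features)
    if (!is.null(rn) && !identical(rn, rownames(family[[1]]$features)))
      stop("participant sets differ across models in the family")
  }
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  fold_id <- fold_assignment(n, scheme, k, seed)

  counts_pos <- matrix(0L, p, n_perm + 1)
  counts_neg <- matrix(0L, p, n_perm + 1)
  for (m in family) {
    Y <- cbind(m$outcome, matrix(m$outcome[perms], nrow = n))
    eng <- cpp_scpm_engine(as.matrix(m$features), Y, as.integer(fold_id),
                           p_thresh, detail = FALSE)
    counts_pos <- counts_pos + eng$everyfold_pos
    counts_neg <- counts_neg + eng$everyfold_neg
  }
  pval <- function(counts) {
    obs <- counts[, 1]
    null <- counts[, -1, drop = FALSE]
    vapply(seq_len(p), function(j)
      (1 + sum(null[j, ] >= obs[j])) / (1 + n_perm), numeric(1))
  }
  tab <- rbind(
    data.frame(cluster = cl_names, sign = "pos",
               observed = counts_pos[, 1], p = pval(counts_pos)),
    data.frame(cluster = cl_names, sign = "neg",
               observed = counts_neg[, 1], p = pval(counts_neg)))
  rownames(tab) <- NULL
  structure(list(table = tab, null_pos = counts_pos[, -1, drop = FALSE],
                 null_neg = counts_neg[, -1, drop = FALSE],
                 family_size = length(family),
                 labels = vapply(family, function(m)
                   if (is.null(m$label)) NA_character_ else m$label,
                   character(1)),
                 n_perm = n_perm, seed = seed),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> family of %d models, %d linked shuffles\n",
              x$family_size, x$n_perm))
  sig <- x$table[x$table$observed > 0, , drop = FALSE]
  print(utils::head(sig[order(sig$p), ], 10))
  invisible(x)
}

#' Anatomically overlapping every-fold clusters across seeds
#'
#' Groups clusters from different seed ROIs whose voxel sets share at least
#' `min_overlap` voxels, restricted to the every-fold-selected clusters of
#' each seed's models.
#'
#' @param cluster_sets Named list (per seed) of [clusterize()] results on a
#'   common grid.
#' @param everyfold_ids Named list (per seed) of every-fold cluster id
#'   vectors (integer ids or `"c<id>"` names).
#' @param min_overlap Minimum shared voxel count.
#' @return List of overlap groups; each group is a data.frame with columns
#'   `seed`, `cluster`, `size`.
#' @export
seed_overlap <- function(cluster_sets, everyfold_ids, min_overlap = 1) {
  seeds <- names(cluster_sets)
  stopifnot(!is.null(seeds), all(seeds %in% names(everyfold_ids)))
  dims <- cluster_sets[[1]]$grid_dims
  nodes <- list()
  for (sd_name in seeds) {
    cs <- cluster_sets[[sd_name]]
    if (!all(cs$grid_dims == dims)) stop("cluster sets on different grids")
    ids <- everyfold_ids[[sd_name]]
    ids <- as.integer(gsub("^c", "", as.character(ids)))
    for (cl in cs$clusters) {
      if (!(cl$id %in% ids)) next
      nodes[[length(nodes) + 1]] <- list(seed = sd_name, id = cl$id,
                                         vox = cl$lin_idx)
    }
  }
  nn <- length(nodes)
  if (nn == 0) return(list())
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      if (nodes[[i]]$seed == nodes[[j]]$seed) next
      if (length(intersect(nodes[[i]]$vox, nodes[[j]]$vox)) >= min_overlap) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  groups <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) < 2) next
    groups[[length(groups) + 1]] <- do.call(rbind, lapply(members, function(i)
      data.frame(seed = nodes[[i]]$seed, cluster = nodes[[i]]$id,
                 size = length(nodes[[i]]$vox))))
  }
  groups
}
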