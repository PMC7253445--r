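# Independent brute-force reference implementations used as oracles. These
# deliberately re-derive every quantity with plain R loops and base stats,
# sharing no code with the package's computational paths.

# Spearman via explicit rank transform + Pearson.
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# Partial Spearman via two explicit regressions on covariate ranks.
oracle_partial_spearman <- function(x, y, Z) {
  rz <- apply(as.matrix(Z), 2, rank)
  ex <- resid(lm(rank(x) ~ rz))
  ey <- resid(lm(rank(y) ~ rz))
  cor(ex, ey)
}

# Largest-drop rule, re-stated from scratch (gaps at 1e-9 resolution).
oracle_largest_drop <- function(r) {
  ok <- which(!is.na(r))
  if (length(ok) == 1) return(ok)
  ord <- ok[order(-round(abs(r[ok]), 9))]
  v <- abs(r[ord])
  gaps <- v[-length(v)] - v[-1]
  ord[seq_len(which.max(round(gaps, 9)))]
}

# Full nested-loop sCPM cross-validation, refit from scratch per fold.
oracle_scpm_cv <- function(X, y, p_thresh = 0.05,
                           fold_id = seq_len(nrow(X))) {
  n <- nrow(X)
  p <- ncol(X)
  K <- max(fold_id)
  pred <- matrix(NA_real_, n, 3)
  sel_all <- matrix(0L, K, p)
  for (f in seq_len(K)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    m <- length(tr)
    r <- rep(NA_real_, p)
    for (j in seq_len(p)) {
      if (sd(X[tr, j]) > 0) r[j] <- cor(rank(X[tr, j]), rank(y[tr]))
    }
    pv <- 2 * pt(-abs(r * sqrt((m - 2) / (1 - r^2))), m - 2)
    sel <- which(!is.na(pv) & pv < p_thresh)
    if (length(sel) == 0 && any(!is.na(r))) sel <- oracle_largest_drop(r)
    pos <- sel[r[sel] >= 0]
    neg <- sel[r[sel] < 0]
    sel_all[f, pos] <- 1L
    sel_all[f, neg] <- -1L
    prd <- function(ids) {
      if (length(ids) == 0) return(rep(mean(y[tr]), length(te)))
      st <- rowMeans(X[, ids, drop = FALSE])
      if (var(st[tr]) * (m - 1) <= 1e-12) return(rep(mean(y[tr]), length(te)))
      cf <- coef(lm(y[tr] ~ st[tr]))
      cf[1] + cf[2] * st[te]
    }
    pred[te, 1] <- prd(pos)
    pred[te, 2] <- prd(neg)
    pred[te, 3] <- if (length(pos) == 0 || length(neg) == 0) {
      prd(if (length(pos) > 0) pos else neg)
    } else {
      sp <- rowMeans(X[, pos, drop = FALSE])
      sn <- rowMeans(X[, neg, drop = FALSE])
      cf <- coef(lm(y[tr] ~ sp[tr] + sn[tr]))
      if (any(is.na(cf))) prd(pos) else cf[1] + cf[2] * sp[te] + cf[3] * sn[te]
    }
  }
  list(pred = pred, sel = sel_all)
}

# Connected components under face adjacency by union-find over voxel pairs.
oracle_components <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  coords <- arrayInd(idx, dims)
  nn <- length(idx)
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(nn)) {
    for (j in seq_len(nn)) {
      if (j <= i) next
      if (sum(abs(coords[i, ] - coords[j, ])) == 1) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  lapply(unique(roots), function(r) sort(idx[roots == r]))
}

# Small planted feature dataset shortcut for model-level tests.
planted_dataset <- function(seed, n = 60, p = 73, beta = 1, noise = 0.3) {
  generate_feature_dataset(sim_feature_config(
    n_participants = n, n_clusters = p, beta = beta, noise_sd = noise,
    seed = seed))
}
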