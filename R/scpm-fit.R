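# Seed connectome-based predictive modeling: correlation-threshold feature
# selection into positive/negative networks inside cross-validation, linear
# network-strength models, and nonparametric permutation significance.

spearman_p_approx <- function(r, n) {
  # two-sided p from the t approximation, the selection rule used in-fold
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks on ties).
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 3).
#' @return Spearman's r_s; `NA` if either vector is constant (flagged with a
#'   warning).
#' @export
predictive_power <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  r <- cpp_spearman(as.numeric(predicted), as.numeric(observed))
  if (is.na(r)) warning("Spearman correlation undefined (constant vector)")
  r
}

#' Correlation-threshold feature selection
#'
#' Correlates every feature column with the outcome (Spearman, two-sided p
#' from the t approximation) and assigns columns with `p < p_thresh` to the
#' positive (r_s > 0) or negative (r_s < 0) network. When no column passes,
#' the largest-drop fallback ([largest_drop_select()]) is invoked. Constant
#' columns are skipped with a message.
#'
#' @param features Training feature matrix (rows = participants).
#' @param outcome Training outcome vector.
#' @param p_thresh Selection threshold.
#' @return List with `pos_ids`, `neg_ids` (column indices), `r_s` (per
#'   column), and `fallback` flag.
#' @export
spearman_select <- function(features, outcome, p_thresh = 0.05) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n >= 4, length(outcome) == n)
  r <- vapply(seq_len(ncol(features)), function(j) {
    if (sd(features[, j]) == 0) return(NA_real_)
    cpp_spearman(features[, j], outcome)
  }, numeric(1))
  n_const <- sum(is.na(r))
  if (n_const > 0)
    message(sprintf("%d constant column(s) skipped in selection", n_const))
  p <- spearman_p_approx(r, n)
  sel <- !is.na(p) & p < p_thresh
  fallback <- FALSE
  if (!any(sel) && any(!is.na(r))) {
    ids <- largest_drop_select(r)
    sel <- seq_along(r) %in% c(ids$pos_ids, ids$neg_ids)
    fallback <- TRUE
  }
  list(pos_ids = which(sel & r > 0), neg_ids = which(sel & r < 0),
       r_s = r, p = p, fallback = fallback)
}

#' Largest-drop fallback selection
#'
#' Ranks |r_s| from strongest to weakest, computes differences between
#' successive coefficients, and keeps every cluster above the largest drop
#' (first occurrence on tied drops; all-equal coefficients keep only the
#' strongest). Selected clusters are partitioned by sign.
#'
#' @param correlations Per-cluster correlation coefficients (`NA` allowed for
#'   undefined columns).
#' @return List with `pos_ids` and `neg_ids`.
#' @export
largest_drop_select <- function(correlations) {
  ok <- which(!is.na(correlations))
  if (length(ok) == 0) return(list(pos_ids = integer(0), neg_ids = integer(0)))
  if (length(ok) == 1) {
    ids <- ok
  } else {
    ord <- ok[order(-round(abs(correlations[ok]), 9))]
    v <- abs(correlations[ord])
    gaps <- v[-length(v)] - v[-1]
    # 1e-9 resolution: exact rational ties in rank correlations must break
    # to the first (strongest) position, not to floating-point noise
    X <- which.max(round(gaps, 9))
    ids <- ord[seq_len(X)]
  }
  list(pos_ids = ids[correlations[ids] >= 0],
       neg_ids = ids[correlations[ids] < 0])
}

#' Mean network strength
#'
#' @param feature_row Numeric vector of one participant's cluster features.
#' @param ids Indices of the network's clusters (non-empty).
#' @return Arithmetic mean over `ids`.
#' @export
network_strength <- function(feature_row, ids) {
  if (length(ids) == 0)
    stop("undefined network: no clusters selected (model non-predictive)")
  mean(feature_row[ids])
}

fold_assignment <- function(n, scheme, k, seed) {
  if (scheme == "loo") return(seq_len(n) - 1L)
  if (k < 2 || k > n) stop("k must be in [2, n]")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n)) - 1L
}

#' Fit a seed connectome-based predictive model
#'
#' Cross-validated sCPM: per fold, features are selected on the training rows
#' ([spearman_select()]), separate univariate linear models of the outcome on
#' mean positive- and negative-network strength are fit (plus a combined
#' two-predictor model), and the held-out rows are predicted. Predictive
#' power is the Spearman correlation of predicted with observed outcomes.
#' With `n_perm > 0`, the whole procedure is re-run on outcome vectors
#' shuffled across participants (selection inside folds each time) to build
#' the permutation null, and one-sided p-values (`#null >= observed`, plus-one
#' estimator) are reported per network.
#'
#' @param features Participants x clusters numeric matrix.
#' @param outcome Numeric outcome vector aligned to rows.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param p_thresh In-fold selection threshold.
#' @param n_perm Number of outcome permutations (0 = skip inference).
#' @param seed Integer seed governing fold assignment and permutations.
#' @return Object of class `scpm_result`: predictions per network, observed
#'   outcomes, `r_s`, per-fold selections and coefficients, every-fold
#'   cluster sets, permutation null and p-values.
#' @export
scpm_fit <- function(features, outcome, scheme = c("loo", "kfold"), k = 10,
                     p_thresh = 0.05, n_perm = 0, seed = 1) {
  scheme <- match.arg(scheme)
  features <- as.matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  stopifnot(n >= 4, length(outcome) == n)
  if (any(!is.finite(features))) stop("features must be finite")
  if (any(!is.finite(outcome))) stop("outcome must be finite")
  fold_id <- fold_assignment(n, scheme, k, seed)

  Y <- matrix(outcome, ncol = 1)
  if (n_perm > 0) {
    set.seed(seed + 1L)
    perms <- replicate(n_perm, sample.int(n))
    Y <- cbind(Y, matrix(outcome[perms], nrow = n))
  }
  eng <- cpp_scpm_engine(features, Y, as.integer(fold_id), p_thresh,
                         detail = TRUE)
  rs_obs <- eng$rs[, 1]
  names(rs_obs) <- c("pos", "neg", "combined")
  cl_names <- colnames(features)
  if (is.null(cl_names)) cl_names <- paste0("c", seq_len(p))
  everyfold <- list(pos = cl_names[eng$everyfold_pos[, 1]],
                    neg = cl_names[eng$everyfold_neg[, 1]])
  sel <- eng$selection
  colnames(sel) <- cl_names
  folds <- lapply(seq_len(max(fold_id) + 1), function(f) {
    list(held_out = which(fold_id == f - 1L),
         pos_ids = which(sel[f, ] == 1L), neg_ids = which(sel[f, ] == -1L),
         r_s = eng$fold_corr[f, ],
         coef = c(pos_intercept = eng$fold_coef[f, 1],
                  pos_slope = eng$fold_coef[f, 2],
                  neg_intercept = eng$fold_coef[f, 3],
                  neg_slope = eng$fold_coef[f, 4]),
         fallback = eng$fallback[f])
  })
  out <- list(predicted = structure(eng$predicted,
                                    dimnames = list(rownames(features),
                                                    c("pos", "neg", "combined"))),
              observed = outcome, r_s = rs_obs, selection = sel,
              folds = folds, everyfold = everyfold, scheme = scheme,
              p_thresh = p_thresh, seed = seed, n_perm = n_perm,
              fold_id = fold_id + 1L)
  if (n_perm > 0) {
    null_rs <- t(eng$rs[, -1, drop = FALSE])
    colnames(null_rs) <- c("pos", "neg", "combined")
    pvals <- vapply(1:3, function(i) {
      (1 + sum(null_rs[, i] >= rs_obs[i], na.rm = TRUE)) / (1 + n_perm)
    }, numeric(1))
    names(pvals) <- c("pos", "neg", "combined")
    out$null_rs <- null_rs
    out$p_value <- pvals
  }
  structure(out, class = "scpm_result")
}

#' @export
print.scpm_result <- function(x, ...) {
  cat(sprintf("<scpm_result> %s CV, n = %d, %d clusters\n", x$scheme,
              length(x$observed), ncol(x$selection)))
  cat(sprintf("  predictive r_s: pos %.3f, neg %.3f, combined %.3f\n",
              x$r_s["pos"], x$r_s["neg"], x$r_s["combined"]))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p (%d shuffles): pos %.4g, neg %.4g\n",
                x$n_perm, x$p_value["pos"], x$p_value["neg"]))
  cat(sprintf("  every-fold clusters: pos {%s}, neg {%s}\n",
              paste(x$everyfold$pos, collapse = ","),
              paste(x$everyfold$neg, collapse = ",")))
  invisible(x)
}

#' Permutation p-value for an sCPM model
#'
#' Convenience wrapper around [scpm_fit()] with `n_perm` permutations.
#'
#' @inheritParams scpm_fit
#' @param network Which network's p-value to report.
#' @return List with `p`, `null` (the null r_s array), and the full fit.
#' @export
permutation_pvalue <- function(features, outcome, n_perm = 1000, seed = 1,
                               scheme = c("loo", "kfold"), k = 10,
                               p_thresh = 0.05,
                               network = c("pos", "neg", "combined")) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  network <- match.arg(network)
  fit <- scpm_fit(features, outcome, scheme = scheme, k = k,
                  p_thresh = p_thresh, n_perm = n_perm, seed = seed)
  list(p = unname(fit$p_value[network]), null = fit$null_rs[, network],
       fit = fit)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all variables (average ranks on ties), residualizes the
#' ranks of `x` and `y` on the covariate ranks by linear regression, and
#' correlates the residuals. With no covariates this is plain Spearman.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/vector of covariates.
#' @return List with `r_s`, `p` (two-sided t approximation, df reduced by the
#'   number of covariates) and `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    r <- cpp_spearman(x, y)
    df <- n - 2
  } else {
    Z <- as.matrix(covariates)
    stopifnot(nrow(Z) == n)
    if (n < ncol(Z) + 3) stop("need at least k + 3 observations")
    Zr <- apply(Z, 2, rank)
    qz <- qr(cbind(1, Zr))
    if (qz$rank < ncol(Zr) + 1)
      warning("collinear covariates dropped in partial correlation")
    rx <- qr.resid(qz, rank(x))
    ry <- qr.resid(qz, rank(y))
    # residuals indistinguishable from zero (variable collinear with the
    # covariates) define a zero partial correlation
    tiny <- 1e-8 * n^1.5
    if (sqrt(sum(rx^2)) < tiny || sqrt(sum(ry^2)) < tiny) {
      r <- 0
    } else {
      r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    }
    df <- n - 2 - qz$rank + 1
  }
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r_s = r, p = 2 * pt(-abs(tt), df = df), df = df)
}

#' Enumerate the sCPM model family
#'
#' The full factorial of seed (full hippocampus, anterior, posterior) x
#' window (all image runs, early only) x reference (stressor minus baseline,
#' or its contrast against the neutral condition) for one outcome: 12 model
#' specifications in a deterministic order.
#'
#' @param outcome Outcome label attached to every spec.
#' @param seeds,windows,references Factor levels.
#' @return data.frame of model specifications.
#' @export
enumerate_model_specs <- function(outcome = "stress",
                                  seeds = c("full", "aHPC", "pHPC"),
                                  windows = c("all", "early"),
                                  references = c("sb", "sbnb")) {
  specs <- expand.grid(seed = seeds, window = windows, reference = references,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  specs <- specs[order(match(specs$seed, seeds), match(specs$window, windows),
                       match(specs$reference, references)), ]
  rownames(specs) <- NULL
  specs$outcome <- outcome
  specs
}

#' Bonferroni-corrected per-model alpha
#'
#' @param family_size Number of models in the family (>= 1).
#' @param fwer Family-wise error rate.
#' @return Per-model alpha, reported at 4 decimals.
#' @export
bonferroni_alpha <- function(family_size, fwer = 0.05) {
  stopifnot(family_size >= 1)
  round(fwer / family_size, 4)
}

#' Classify how a predictive network responds to the stressor
#'
#' A positive-network cluster (higher connectivity predicts more stress)
#' whose group-mean connectivity decreased under the stressor responds
#' consistent with attenuating feelings of stress; an increase is amplifying.
#' The mapping is mirrored for negative networks. A network whose clusters
#' are directionally mixed (less than `consistency` of them sharing a label)
#' is classified random.
#'
#' @param mean_change Per-cluster group-mean stressor-vs-neutral connectivity
#'   change.
#' @param network_sign `"pos"` or `"neg"`.
#' @param consistency Proportion of same-label clusters required before the
#'   network-level label is not `"random"`.
#' @return List with per-cluster labels and the network-level label.
#' @export
classify_network_response <- function(mean_change,
                                      network_sign = c("pos", "neg"),
                                      consistency = 0.75) {
  network_sign <- match.arg(network_sign)
  lab <- ifelse(mean_change < 0,
                if (network_sign == "pos") "attenuating" else "amplifying",
                if (network_sign == "pos") "amplifying" else "attenuating")
  lab[mean_change == 0] <- "random"
  tab <- table(factor(lab, levels = c("attenuating", "amplifying", "random")))
  top <- names(tab)[which.max(tab)]
  network <- if (max(tab) / length(lab) >= consistency) top else "random"
  list(cluster = lab, network = network)
}
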