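# The predictive-modeling core: selection, fallback, network strength,
# cross-validation (against a from-scratch nested-loop oracle), permutation
# inference, partial correlations and the model-family bookkeeping.

test_that("threshold selection assigns monotone columns to the right network", {
  set.seed(11)
  y <- rnorm(59)
  X <- matrix(rnorm(59 * 5), 59, 5)
  X[, 2] <- exp(y)      # strictly increasing transform
  X[, 4] <- -y
  X[, 5] <- 1           # constant -> skipped
  sel <- suppressMessages(spearman_select(X, y))
  expect_true(2 %in% sel$pos_ids)
  expect_true(4 %in% sel$neg_ids)
  expect_equal(sel$r_s[2], 1)
  expect_equal(sel$r_s[4], -1)
  expect_true(is.na(sel$r_s[5]))
})

test_that("null selection rate matches the nominal threshold", {
  counts <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(59 * 73), 59, 73)
    y <- rnorm(59)
    sel <- spearman_select(X, y)
    if (sel$fallback) 0L else length(sel$pos_ids) + length(sel$neg_ids)
  }, integer(1))
  expect_gt(mean(counts), 2.6)
  expect_lt(mean(counts), 4.6)
})

test_that("largest-drop fallback implements the gap rule", {
  out <- largest_drop_select(c(0.9, 0.8, 0.3, 0.2))
  expect_identical(sort(c(out$pos_ids, out$neg_ids)), 1:2)
  out2 <- largest_drop_select(c(0.9, 0.4, 0.35, 0.3))
  expect_identical(c(out2$pos_ids, out2$neg_ids), 1L)
  out3 <- largest_drop_select(c(0.5, -0.5, 0.5, -0.5))  # all-equal gaps
  expect_identical(length(c(out3$pos_ids, out3$neg_ids)), 1L)
  out4 <- largest_drop_select(c(-0.9, 0.2, -0.85))
  expect_identical(out4$neg_ids, c(1L, 3L))

  set.seed(12)
  for (i in 1:1000) {
    r <- round(runif(sample(2:10, 1), -1, 1), 3)
    got <- largest_drop_select(r)
    expect_identical(sort(c(got$pos_ids, got$neg_ids)),
                     sort(oracle_largest_drop(r)))
  }
})

test_that("network strength is the mean over selected clusters", {
  row <- c(a = 1.0, b = 3.0, c = -2.0)
  expect_identical(network_strength(row, 2), 3.0)
  expect_identical(network_strength(row, c(1, 2)), 2.0)
  expect_identical(network_strength(row, c(2, 1)), 2.0)
  expect_error(network_strength(row, integer(0)), "non-predictive")
})

test_that("LOO cross-validation equals the from-scratch nested-loop oracle", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(8:20, 1)
    p <- sample(2:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n) + X[, 1] * runif(1, 0, 1.5)
    fit <- scpm_fit(X, y, seed = 1)
    br <- oracle_scpm_cv(X, y)
    expect_identical(unname(fit$selection), br$sel)
    expect_equal(unname(fit$predicted), br$pred, tolerance = 1e-10)
  }
})

test_that("k-fold CV is deterministic in its seed and matches the oracle", {
  set.seed(14)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30) + X[, 2]
  f1 <- scpm_fit(X, y, scheme = "kfold", k = 10, seed = 11)
  f2 <- scpm_fit(X, y, scheme = "kfold", k = 10, seed = 11)
  expect_identical(f1$fold_id, f2$fold_id)
  expect_identical(f1$predicted, f2$predicted)
  br <- oracle_scpm_cv(X, y, fold_id = f1$fold_id)
  expect_equal(unname(f1$predicted), br$pred, tolerance = 1e-10)
})

test_that("noise-free planted data give perfect positive-network prediction", {
  # outcome is an exact linear function of the positive-network strength, so
  # with the planted clusters as the whole feature space the LOO predictions
  # recover the ranks exactly
  ds <- generate_feature_dataset(sim_feature_config(
    n_participants = 30, n_clusters = 2, pos_ids = 1:2,
    neg_ids = integer(0), beta = 1, noise_sd = 0, seed = 15))
  fit <- scpm_fit(ds$features, ds$outcome, seed = 1)
  expect_equal(unname(fit$r_s["pos"]), 1.0)
  expect_setequal(fit$everyfold$pos, c("c1", "c2"))
})

test_that("predictive power is Spearman with midranks", {
  expect_equal(predictive_power(1:10, 1:10), 1.0)
  expect_equal(predictive_power(10:1, 1:10), -1.0)
  set.seed(16)
  for (i in 1:1000) {
    n <- sample(4:15, 1)
    a <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01)
    b <- c(1, 2, sample(1:4, n - 2, replace = TRUE))  # never constant
    expect_equal(predictive_power(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(predictive_power(rep(1, 5), 1:5), "constant")
})

test_that("no information leaks from the held-out participant", {
  set.seed(17)
  ds <- planted_dataset(seed = 18, n = 20, p = 10)
  fit <- scpm_fit(ds$features, ds$outcome, seed = 1)
  y2 <- ds$outcome
  y2[7] <- y2[7] + 100  # corrupt only the held-out value of fold 7
  fit2 <- scpm_fit(ds$features, y2, seed = 1)
  expect_identical(fit$selection[7, ], fit2$selection[7, ])
  expect_identical(fit$folds[[7]]$coef, fit2$folds[[7]]$coef)
})

test_that("permutation p-values use the plus-one rule and detect signal", {
  ds <- generate_feature_dataset(sim_feature_config(
    n_participants = 24, n_clusters = 6, pos_ids = 1:2, neg_ids = 3:4,
    beta = 2, noise_sd = 0, seed = 19))
  pp <- permutation_pvalue(ds$features, ds$outcome, n_perm = 1000, seed = 4)
  # noise-free planted signal beats every shuffle
  expect_equal(pp$p, 1 / 1001)
  expect_identical(length(pp$null), 1000L)
  expect_error(permutation_pvalue(ds$features, ds$outcome, n_perm = 10),
               "at least 100")
})

test_that("planted models stay significant with realistic noise", {
  # planted-validation configuration: 16 clusters keeps expected false
  # selections per fold (~0.3) well below the planted network size
  hits <- vapply(1:10, function(s) {
    ds <- planted_dataset(seed = 300 + s, p = 16)
    fit <- scpm_fit(ds$features, ds$outcome, n_perm = 1000, seed = s)
    fit$p_value["pos"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("network models outperform the best single cluster on planted data", {
  wins <- vapply(1:20, function(s) {
    ds <- generate_feature_dataset(sim_feature_config(
      n_participants = 40, n_clusters = 12, pos_ids = 1:4,
      neg_ids = integer(0), beta = 1.5, noise_sd = 0.5, seed = 600 + s))
    fit <- scpm_fit(ds$features, ds$outcome, seed = 1)
    best_single <- max(vapply(1:4, function(j) {
      pred <- vapply(seq_along(ds$outcome), function(i) {
        cf <- coef(lm(ds$outcome[-i] ~ ds$features[-i, j]))
        cf[1] + cf[2] * ds$features[i, j]
      }, numeric(1))
      cor(pred, ds$outcome, method = "spearman")
    }, numeric(1)))
    fit$r_s["pos"] >= best_single
  }, logical(1))
  expect_gte(mean(wins), 0.80)
})

test_that("partial Spearman matches the two-regression oracle", {
  set.seed(20)
  x <- rnorm(30)
  y <- rnorm(30)
  expect_equal(partial_spearman(x, y)$r_s, oracle_spearman(x, y),
               tolerance = 1e-12)
  z <- rnorm(30)
  expect_lt(abs(partial_spearman(x, z, covariates = z)$r_s), 1e-10)
  for (i in 1:500) {
    n <- sample(10:25, 1)
    k <- sample(1:3, 1)
    x <- rnorm(n)
    Z <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n) + Z %*% rnorm(k)
    expect_equal(partial_spearman(x, y, Z)$r_s,
                 oracle_partial_spearman(x, y, Z), tolerance = 1e-10)
  }
})

test_that("the model family enumerates 12 distinct specifications", {
  specs <- enumerate_model_specs("stress")
  expect_identical(nrow(specs), 12L)
  expect_identical(anyDuplicated(specs[, c("seed", "window", "reference")]),
                   0L)
  one_seed <- specs[specs$seed == "aHPC", ]
  expect_identical(nrow(one_seed), 4L)
  expect_identical(nrow(enumerate_model_specs("arousal")), 12L)
})

test_that("Bonferroni arithmetic reports four decimals", {
  expect_identical(bonferroni_alpha(12), 0.0042)
  expect_identical(bonferroni_alpha(1), 0.05)
  expect_identical(bonferroni_alpha(20), 0.0025)
})

test_that("network responses classify as amplifying, attenuating or random", {
  expect_identical(classify_network_response(-0.2, "pos")$cluster,
                   "attenuating")
  expect_identical(classify_network_response(0.2, "neg")$cluster,
                   "attenuating")
  expect_identical(classify_network_response(0.2, "pos")$cluster,
                   "amplifying")
  mixed <- classify_network_response(c(0.3, -0.3, 0.2, -0.2), "pos")
  expect_identical(mixed$network, "random")
  consistent <- classify_network_response(c(-0.3, -0.2, -0.25, -0.1), "pos")
  expect_identical(consistent$network, "attenuating")
})
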