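# Every-fold cluster sets, linked-shuffle consistency inference and
# cross-seed cluster overlap.

test_that("every-fold sets are the intersection of per-fold selections", {
  ds <- generate_feature_dataset(sim_feature_config(
    n_participants = 20, n_clusters = 8, pos_ids = 1:2, neg_ids = 3:4,
    beta = 1.5, noise_sd = 0.2, seed = 30))
  fit <- scpm_fit(ds$features, ds$outcome, seed = 1)
  ef <- everyfold_clusters(fit)
  # brute-force set intersection over the fold records
  oracle_pos <- colnames(fit$selection)[colSums(fit$selection == 1) ==
                                          nrow(fit$selection)]
  oracle_neg <- colnames(fit$selection)[colSums(fit$selection == -1) ==
                                          nrow(fit$selection)]
  expect_setequal(ef$pos, oracle_pos)
  expect_setequal(ef$neg, oracle_neg)
  # a cluster missing from one fold is excluded by construction
  if (length(oracle_pos) > 0) {
    drop_one <- fit$selection
    drop_one[1, oracle_pos[1]] <- 0L
    expect_false(oracle_pos[1] %in%
                   colnames(drop_one)[colSums(drop_one == 1) == nrow(drop_one)])
  }
})

test_that("linked shuffles apply one relabeling to every outcome", {
  ds <- generate_feature_dataset(sim_feature_config(
    n_participants = 16, n_clusters = 6, pos_ids = 1, neg_ids = 2,
    beta = 1, noise_sd = 0.3, seed = 31))
  # two models with *identical* outcomes: under a linked shuffle their null
  # every-fold sets must coincide permutation by permutation
  fam <- list(list(features = ds$features, outcome = ds$outcome, label = "a"),
              list(features = ds$features, outcome = ds$outcome, label = "b"))
  res <- consistency_permutation_test(fam, n_perm = 50, seed = 5)
  expect_true(all(res$null_pos %% 2 == 0))
  expect_true(all(res$null_neg %% 2 == 0))
  expect_true(all(res$table$observed %% 2 == 0))
})

test_that("a cluster driving every outcome is flagged as consistent", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    X <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(NULL, paste0("c", 1:10)))
    fam <- lapply(1:4, function(m)
      list(features = X, outcome = X[, 1] + rnorm(30, sd = 0.3),
           label = paste0("m", m)))
    res <- consistency_permutation_test(fam, n_perm = 200, seed = s)
    res$table$p[res$table$cluster == "c1" & res$table$sign == "pos"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("linked shuffles preserve inter-outcome correlation, break brain links", {
  set.seed(32)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5)
  y1 <- rnorm(n)
  y2 <- y1 + rnorm(n, sd = 0.2)
  perm <- sample.int(n)
  expect_equal(cor(y1[perm], y2[perm]), cor(y1, y2))
  # feature-outcome correlation is near zero in expectation under relabeling
  rs <- replicate(200, {
    p <- sample.int(n)
    cor(X[, 1], y1[p])
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("consistency p-values are monotone in the observed count", {
  null_counts <- matrix(rep(c(0L, 1L, 2L, 4L), each = 3), nrow = 3)
  p_of <- function(obs) (1 + sum(null_counts[1, ] >= obs)) / (1 + ncol(null_counts))
  ps <- vapply(0:4, p_of, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("family validation rejects mismatched participant sets", {
  X1 <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  X2 <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("t", 1:5), NULL))
  fam <- list(list(features = X1, outcome = rnorm(5)),
              list(features = X2, outcome = rnorm(5)))
  expect_error(consistency_permutation_test(fam, n_perm = 100),
               "participant sets differ")
})

test_that("cross-seed overlap matches a pairwise intersection oracle", {
  dims <- c(8, 8, 4)
  mk_cs <- function(vox_list) {
    clusters <- lapply(seq_along(vox_list), function(i)
      list(id = i, lin_idx = vox_list[[i]],
           voxels = arrayInd(vox_list[[i]], dims), sign = 1,
           size = length(vox_list[[i]]),
           peak = drop(arrayInd(vox_list[[i]][1], dims))))
    structure(list(clusters = clusters, grid_dims = dims, voxel_p = 0.001),
              class = "cluster_set")
  }
  cs_a <- mk_cs(list(1:5, 20:24))
  cs_b <- mk_cs(list(3:7, 40:44))
  # identical voxel sets in two seeds form one group
  g_same <- seed_overlap(list(full = cs_a, aHPC = cs_a),
                         list(full = 1:2, aHPC = 1:2))
  expect_identical(length(g_same), 2L)
  # partial overlap c(1:5) vs c(3:7) groups; disjoint 20:24 vs 40:44 do not
  g <- seed_overlap(list(full = cs_a, aHPC = cs_b),
                    list(full = 1:2, aHPC = 1:2))
  expect_identical(length(g), 1L)
  expect_setequal(g[[1]]$seed, c("full", "aHPC"))
  g_none <- seed_overlap(list(full = mk_cs(list(1:5)),
                              aHPC = mk_cs(list(60:64))),
                         list(full = 1, aHPC = 1))
  expect_identical(length(g_none), 0L)

  # random sets against a brute-force pairwise oracle
  set.seed(33)
  for (i in 1:10) {
    va <- lapply(1:3, function(j) sample(1:256, 8))
    vb <- lapply(1:3, function(j) sample(1:256, 8))
    g <- seed_overlap(list(A = mk_cs(va), B = mk_cs(vb)),
                      list(A = 1:3, B = 1:3))
    brute_pairs <- sum(vapply(1:3, function(a) sum(vapply(1:3, function(b)
      length(intersect(va[[a]], vb[[b]])) >= 1, logical(1))), numeric(1)))
    # every overlapping pair must co-occur in some group
    in_group <- sum(vapply(g, function(grp) {
      a_ids <- grp$cluster[grp$seed == "A"]
      b_ids <- grp$cluster[grp$seed == "B"]
      sum(vapply(a_ids, function(a) sum(vapply(b_ids, function(b)
        length(intersect(va[[a]], vb[[b]])) >= 1, logical(1))), numeric(1)))
    }, numeric(1)))
    expect_identical(in_group, brute_pairs)
  }
})
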