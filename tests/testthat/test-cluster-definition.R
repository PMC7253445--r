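# Group contrasts, bi-sided NN1 clustering, permutation extent thresholds
# and cluster-mean features.

mk_gsm <- function(stat, p = NULL, n = 20) {
  if (is.null(p)) p <- array(ifelse(stat != 0, 1e-6, 1), dim = dim(stat))
  structure(list(stat = stat, p = p, n_participants = n, df = n - 1,
                 contrast = "Stressor vs Neutral"), class = "group_stat_map")
}

diff_matrix <- function(maps) {
  D <- t(vapply(maps, as.numeric, numeric(length(maps[[1]]))))
  attr(D, "grid_dims") <- dim(maps[[1]])
  D
}

test_that("group contrast is zero for identical conditions and sign-odd", {
  set.seed(7)
  maps <- lapply(1:6, function(i) {
    m <- array(rnorm(60), c(5, 4, 3))
    list(Stressor = list(early = m, mid = m, late = m),
         Neutral = list(early = m, mid = m, late = m))
  })
  g <- group_contrast(maps)
  expect_true(all(g$stat == 0))
  expect_identical(length(clusterize(g, 0.001)$clusters), 0L)

  D <- matrix(rnorm(6 * 60), 6, 60)
  attr(D, "grid_dims") <- c(5, 4, 3)
  Dn <- -D
  attr(Dn, "grid_dims") <- c(5, 4, 3)
  expect_equal(group_contrast(Dn)$stat, -group_contrast(D)$stat)
})

test_that("planted voxel offsets are detected with high power", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    D <- matrix(rnorm(20 * 200, sd = 0.2), 20, 200)
    D[, 1:10] <- D[, 1:10] + 0.5
    attr(D, "grid_dims") <- c(10, 10, 2)
    g <- group_contrast(D)
    all(g$p[1:10] < 0.001 & g$stat[1:10] > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("bi-sided NN1 clustering separates signs and corner contacts", {
  st <- array(0, c(8, 8, 4))
  st[2:3, 2:3, 2] <- 5          # 4-voxel positive slab
  st[2, 2, 3] <- 5              # face-connected above -> one cluster of 5
  cs <- clusterize(mk_gsm(st), 0.001)
  expect_identical(length(cs$clusters), 1L)
  expect_identical(cs$clusters[[1]]$size, 5L)
  expect_identical(cs$clusters[[1]]$sign, 1)

  # corner-touching blobs are distinct under face adjacency
  st2 <- array(0, c(8, 8, 4))
  st2[2, 2, 2] <- 4
  st2[3, 3, 2] <- 4
  expect_identical(length(clusterize(mk_gsm(st2), 0.001)$clusters), 2L)

  # adjacent positive and negative voxels never merge
  st3 <- array(0, c(8, 8, 4))
  st3[2:3, 2, 2] <- 4
  st3[4:5, 2, 2] <- -4
  cs3 <- clusterize(mk_gsm(st3), 0.001)
  expect_identical(length(cs3$clusters), 2L)
  expect_setequal(vapply(cs3$clusters, `[[`, numeric(1), "sign"), c(1, -1))
})

test_that("clustering matches a union-find oracle on random maps", {
  set.seed(8)
  for (i in 1:8) {
    st <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    st[abs(st) < 1.2] <- 0
    cs <- clusterize(mk_gsm(st), 0.001)
    for (sgn in c(1, -1)) {
      oracle <- oracle_components(array(sign(st) == sgn, dim(st)))
      got <- lapply(Filter(function(cl) cl$sign == sgn, cs$clusters),
                    function(cl) sort(cl$lin_idx))
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
    }
    # pairwise disjoint
    all_idx <- unlist(lapply(cs$clusters, `[[`, "lin_idx"))
    expect_identical(anyDuplicated(all_idx), 0L)
  }
})

test_that("cluster ids are deterministic by size then peak coordinate", {
  st <- array(0, c(10, 6, 4))
  st[2:5, 2, 2] <- 3      # size 4
  st[8:9, 4, 3] <- 6      # size 2
  cs <- clusterize(mk_gsm(st), 0.001)
  expect_identical(vapply(cs$clusters, `[[`, integer(1), "size"), c(4L, 2L))
  expect_identical(cs$clusters[[1]]$id, 1L)
})

test_that("extent threshold is degenerate at alpha 1 and monotone in alpha", {
  set.seed(9)
  maps <- lapply(1:8, function(i) array(rnorm(200), c(10, 10, 2)))
  D <- diff_matrix(maps)
  k1 <- cluster_extent_threshold(D, voxel_p = 0.05, alpha = 1.0,
                                 n_perm = 100, seed = 2)
  expect_identical(k1$k, 1L)
  ks <- vapply(c(0.05, 0.2, 0.5, 1.0), function(a)
    cluster_extent_threshold(D, voxel_p = 0.05, alpha = a, n_perm = 100,
                             seed = 2)$k, integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_error(cluster_extent_threshold(D, n_perm = 50), "at least 100")
})

test_that("cluster-mean features reduce to voxel values and cancel on sbnb", {
  set.seed(10)
  dims <- c(6, 6, 4)
  mapset <- function() {
    eps <- c("baseline", "early", "mid", "late")
    stats::setNames(lapply(eps, function(e) array(rnorm(prod(dims)), dims)),
                    eps)
  }
  z_maps <- lapply(stats::setNames(1:5, paste0("sub0", 1:5)), function(i) {
    S <- mapset()
    list(Stressor = S, Neutral = S)  # identical conditions
  })
  st <- array(0, dims)
  st[3, 3, 2] <- 5
  cs <- clusterize(mk_gsm(st), 0.001)
  expect_identical(length(cs$clusters), 1L)
  f_sb <- cluster_mean_features(z_maps, cs, reference = "sb", window = "all")
  expect_identical(dim(f_sb), c(5L, 1L))
  # single-voxel cluster: feature equals that voxel's mean differential
  p1 <- z_maps[[1]]$Stressor
  expected <- mean(vapply(c("early", "mid", "late"), function(e)
    p1[[e]][3, 3, 2] - p1$baseline[3, 3, 2], numeric(1)))
  expect_equal(unname(f_sb[1, 1]), expected)
  # early window
  f_early <- cluster_mean_features(z_maps, cs, "sb", "early")
  expect_equal(unname(f_early[1, 1]), p1$early[3, 3, 2] - p1$baseline[3, 3, 2])
  # identical conditions cancel under sbnb
  f_sbnb <- cluster_mean_features(z_maps, cs, reference = "sbnb")
  expect_equal(unname(f_sbnb[, 1]), rep(0, 5))
})
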