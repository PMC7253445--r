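# Planted-truth generators: determinism, config validation, noise-free
# monotone construction, spectral confinement, ratings contracts.

test_that("feature generator is deterministic and validates its config", {
  cfg <- sim_feature_config(n_participants = 12, n_clusters = 8, seed = 7)
  a <- generate_feature_dataset(cfg)
  b <- generate_feature_dataset(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$outcome, b$outcome)

  expect_error(sim_feature_config(pos_ids = 1:3, neg_ids = 3:4),
               "disjoint")
  expect_error(sim_feature_config(n_participants = 3), "at least 4")
  expect_error(sim_feature_config(noise_sd = -1), "non-negative")
  expect_error(sim_feature_config(n_clusters = 4, pos_ids = 1:2,
                                  neg_ids = 4:5), "1..n_clusters")
})

test_that("noise-free outcome is a monotone function of planted strength", {
  ds <- generate_feature_dataset(sim_feature_config(
    n_participants = 20, n_clusters = 10, pos_ids = 1:2, neg_ids = 3:4,
    beta = 1, noise_sd = 0, seed = 3))
  net <- rowMeans(ds$features[, 1:2]) - rowMeans(ds$features[, 3:4])
  expect_equal(cor(ds$outcome, net, method = "spearman"), 1.0)
  # and against the positive network alone when no negative ids are planted
  ds2 <- generate_feature_dataset(sim_feature_config(
    n_participants = 20, n_clusters = 10, pos_ids = 1:3,
    neg_ids = integer(0), beta = 2, noise_sd = 0, seed = 4))
  expect_equal(cor(ds2$outcome, rowMeans(ds2$features[, 1:3]),
                   method = "spearman"), 1.0)
})

test_that("timeseries generator is deterministic and validates masks", {
  cfg <- sim_timeseries_config(grid_dims = c(18, 18, 8),
                               seed_roi = as.matrix(expand.grid(2:3, 2:3, 2:3)),
                               target_clusters = list(
                                 list(voxels = as.matrix(expand.grid(10:12, 10:12, 4:5)),
                                      coupling_neutral = 0,
                                      coupling_stress = 0.5)),
                               seed = 5)
  a <- generate_timeseries_dataset(cfg)
  b <- generate_timeseries_dataset(cfg)
  expect_identical(a$ts$values, b$ts$values)
  expect_identical(a$confounds$motion6, b$confounds$motion6)

  expect_error(sim_timeseries_config(grid_dims = c(4, 4, 4)),
               "grid too small")
  expect_error(sim_timeseries_config(
    grid_dims = c(18, 18, 8),
    seed_roi = as.matrix(expand.grid(2:3, 2:3, 2:3)),
    target_clusters = list(list(voxels = as.matrix(expand.grid(2:3, 2:3, 2:3)),
                                coupling_neutral = 0, coupling_stress = 0.5))),
    "disjoint")
  expect_error(sim_timeseries_config(
    grid_dims = c(18, 18, 8),
    seed_roi = as.matrix(expand.grid(2:3, 2:3, 2:3)),
    target_clusters = list(list(voxels = as.matrix(expand.grid(10:11, 10:11, 4:5)),
                                coupling_neutral = 0, coupling_stress = 1.5))),
    "couplings")
})

test_that("latent signal is spectrally confined to the passband", {
  for (s in 1:5) {
    set.seed(s)
    sig <- scpm:::band_limited_signal(528, 1, c(0.01, 0.1))
    spec <- Mod(fft(sig))^2
    freqs <- (seq_along(sig) - 1) / 528
    in_band <- (freqs >= 0.009 & freqs <= 0.101) |
      (freqs >= 1 - 0.101 & freqs <= 1 - 0.009)
    expect_gt(sum(spec[in_band]) / sum(spec[-1]), 0.95)
  }
})

test_that("ratings respect scale bounds, drift and determinism", {
  task <- default_task_design()
  r0 <- generate_ratings(6, task, drift = 0, seed = 2, noise_sd = 0)
  em <- epoch_rating_means(r0)
  out <- relative_outcome(em, "mean_stress")
  expect_equal(unname(out), rep(0, 6))
  out_l <- relative_outcome(em, "late_arousal")
  expect_equal(unname(out_l), rep(0, 6))

  extreme <- generate_ratings(5, task, drift = 50, seed = 2)
  expect_true(all(extreme$stress >= 1 & extreme$stress <= 9))
  neg <- generate_ratings(5, task, drift = -50, seed = 2)
  expect_true(all(neg$stress >= 1 & neg$stress <= 9))
  expect_identical(generate_ratings(5, task, drift = 1, seed = 9),
                   generate_ratings(5, task, drift = 1, seed = 9))

  # positive drift raises late stressor ratings above early ones on average
  diffs <- vapply(1:100, function(s) {
    r <- generate_ratings(4, task, drift = 1, seed = s)
    r <- r[r$condition == "Stressor", ]
    mean(r$stress[r$run %in% 7:8]) - mean(r$stress[r$run %in% 3:4])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
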