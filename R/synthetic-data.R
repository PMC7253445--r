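# Synthetic datasets with planted ground truth: feature-level datasets for
# the predictive-modeling stages and small 4D timeseries datasets with known
# seed coupling, task-evoked signal and confounds for the connectivity stages.

#' Configuration for a planted feature-level dataset
#'
#' Defaults mirror the scale of the motivating study design: 60 participants,
#' 73 clusters, two positive and two negative planted network clusters, unit
#' effect size and rating-noise SD 0.3.
#'
#' @param n_participants Number of participants (>= 4).
#' @param n_clusters Number of feature columns.
#' @param pos_ids,neg_ids Disjoint planted cluster indices (1-based).
#' @param beta Effect size (rating units per z unit of network strength).
#' @param noise_sd Outcome noise SD (>= 0).
#' @param seed RNG seed.
#' @return Validated config list of class `sim_feature_config`.
#' @export
sim_feature_config <- function(n_participants = 60, n_clusters = 73,
                               pos_ids = 1:2, neg_ids = 3:4, beta = 1,
                               noise_sd = 0.3, seed = 1) {
  if (n_participants < 4) stop("n_participants must be at least 4")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(intersect(pos_ids, neg_ids)) > 0)
    stop("pos_ids and neg_ids must be disjoint")
  if (any(c(pos_ids, neg_ids) < 1) || any(c(pos_ids, neg_ids) > n_clusters))
    stop("planted ids must lie in 1..n_clusters")
  structure(list(n_participants = n_participants, n_clusters = n_clusters,
                 pos_ids = as.integer(pos_ids), neg_ids = as.integer(neg_ids),
                 beta = beta, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_feature_config")
}

#' Generate a feature-level dataset with planted networks
#'
#' Features are i.i.d. standard normal. The outcome is
#' `beta * mean(features over pos_ids) - beta * mean(features over neg_ids)`
#' plus Gaussian noise, so the planted positive network drives higher
#' outcomes and the planted negative network lower ones.
#'
#' @param cfg A [sim_feature_config()].
#' @return List with `features` (matrix with participant rownames and cluster
#'   colnames), `outcome`, and the config.
#' @export
generate_feature_dataset <- function(cfg = sim_feature_config()) {
  stopifnot(inherits(cfg, "sim_feature_config"))
  set.seed(cfg$seed)
  n <- cfg$n_participants
  p <- cfg$n_clusters
  feat <- matrix(rnorm(n * p), n, p,
                 dimnames = list(sprintf("sub%02d", seq_len(n)),
                                 paste0("c", seq_len(p))))
  signal <- numeric(n)
  if (length(cfg$pos_ids) > 0)
    signal <- signal + cfg$beta * rowMeans(feat[, cfg$pos_ids, drop = FALSE])
  if (length(cfg$neg_ids) > 0)
    signal <- signal - cfg$beta * rowMeans(feat[, cfg$neg_ids, drop = FALSE])
  outcome <- signal + rnorm(n, sd = cfg$noise_sd)
  list(features = feat, outcome = outcome, config = cfg)
}

# Band-limited unit-variance signal: inverse FFT of a white spectrum
# restricted to the passband (exact spectral confinement).
band_limited_signal <- function(n_samp, tr_s, band) {
  freqs <- (seq_len(n_samp) - 1) / (n_samp * tr_s)
  half <- seq(2, floor(n_samp / 2) + 1)
  keep <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  if (length(keep) < 2) stop("run too short to carry band-limited signal")
  spec <- complex(length.out = n_samp)
  amp <- rnorm(length(keep)) + 1i * rnorm(length(keep))
  spec[keep] <- amp
  spec[n_samp - keep + 2] <- Conj(amp)
  s <- Re(fft(spec, inverse = TRUE)) / n_samp
  as.numeric(scale(s))
}

#' Configuration for a synthetic 4D timeseries dataset
#'
#' Defaults reproduce the study-scale session structure on a desk-scale grid:
#' 24 x 24 x 16 voxels of 2 mm, TR 1 s, per condition 2 baseline runs plus 6
#' image runs of 66 s (5-s images, 1-s ISI), band-limited latent seed signal
#' in 0.01-0.1 Hz, task-evoked responses, confound components and white
#' noise. Target clusters couple to the seed during image runs only (baseline
#' coupling is zero), with condition-specific coupling strengths.
#'
#' @param grid_dims Voxel grid dimensions.
#' @param voxel_mm Voxel edge (mm).
#' @param tr_s Repetition time (s).
#' @param run_len_s Run length (s).
#' @param n_baseline_runs,n_image_runs Runs per condition.
#' @param seed_roi 3-column matrix of seed voxel indices (1-based), or `NULL`
#'   for the default block.
#' @param target_clusters List of lists `(voxels, coupling_neutral,
#'   coupling_stress)`; `NULL` for the two default blocks (one positive, one
#'   negative stressor-specific coupling).
#' @param band Passband (Hz) of the latent signal.
#' @param evoked_amp Amplitude of the task-evoked (boxcar x HRF) component.
#' @param confound_amp Amplitude of the confound component added to seed and
#'   cluster voxels.
#' @param noise_sd White-noise SD.
#' @param seed RNG seed.
#' @return Validated config of class `sim_timeseries_config`.
#' @export
sim_timeseries_config <- function(grid_dims = c(24, 24, 16), voxel_mm = 2,
                                  tr_s = 1, run_len_s = 66,
                                  n_baseline_runs = 2, n_image_runs = 6,
                                  seed_roi = NULL, target_clusters = NULL,
                                  band = c(0.01, 0.1), evoked_amp = 1,
                                  confound_amp = 0.5, noise_sd = 0.3,
                                  seed = 1) {
  block <- function(xr, yr, zr) as.matrix(expand.grid(x = xr, y = yr, z = zr))
  if (is.null(seed_roi)) seed_roi <- block(4:6, 10:12, 7:9)
  if (is.null(target_clusters)) {
    target_clusters <- list(
      list(voxels = block(14:16, 6:8, 5:6), coupling_neutral = 0,
           coupling_stress = 0.6),
      list(voxels = block(14:16, 16:18, 10:11), coupling_neutral = 0,
           coupling_stress = -0.5))
  }
  all_vox <- rbind(seed_roi,
                   do.call(rbind, lapply(target_clusters, `[[`, "voxels")))
  if (any(all_vox < 1) || any(t(all_vox) > grid_dims))
    stop("grid too small to host all masks")
  key <- function(v) paste(v[, 1], v[, 2], v[, 3])
  keys <- lapply(target_clusters, function(tc) key(tc$voxels))
  if (any(unlist(keys) %in% key(seed_roi)) || anyDuplicated(unlist(keys)) > 0)
    stop("target clusters must be disjoint from each other and the seed ROI")
  for (tc in target_clusters) {
    if (abs(tc$coupling_neutral) > 1 || abs(tc$coupling_stress) > 1)
      stop("couplings must lie in [-1, 1]")
  }
  structure(list(grid_dims = as.integer(grid_dims), voxel_mm = voxel_mm,
                 tr_s = tr_s, run_len_s = run_len_s,
                 n_baseline_runs = as.integer(n_baseline_runs),
                 n_image_runs = as.integer(n_image_runs),
                 seed_roi = seed_roi, target_clusters = target_clusters,
                 band = band, evoked_amp = evoked_amp,
                 confound_amp = confound_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_timeseries_config")
}

sim_confounds <- function(nt, tr_s, seed_offset = 0) {
  motion6 <- vapply(1:6, function(j) {
    sc <- if (j <= 3) 0.02 else 0.0004
    cumsum(rnorm(nt, sd = sc))
  }, numeric(nt))
  smooth1d <- function(x, w = 5) as.numeric(stats::filter(x, rep(1 / w, w),
                                                          sides = 2)) |>
    (\(v) {v[is.na(v)] <- x[is.na(v)]; v})()
  wm <- smooth1d(rnorm(nt))
  csf <- smooth1d(rnorm(nt))
  global <- smooth1d(rnorm(nt))
  n_out <- max(1, rbinom(1, 3, 0.5))
  frames <- sample.int(nt, n_out)
  outliers <- matrix(0, nt, n_out)
  outliers[cbind(frames, seq_len(n_out))] <- 1
  confound_set(motion6, wm, csf, global, outliers)
}

#' Generate a synthetic 4D timeseries dataset
#'
#' Builds one participant-condition acquisition: seed-ROI voxels carry a
#' shared band-limited latent signal; each target-cluster voxel is
#' `coupling * s(t) + sqrt(1 - coupling^2) * d(t)` (an independent
#' band-limited distractor, so the planted in-band correlation with the seed
#' equals the coupling) plus the task-evoked response, a confound component
#' and white noise; all remaining voxels are pure white noise.
#'
#' @param cfg A [sim_timeseries_config()].
#' @param condition `"Stressor"` or `"Neutral"` (selects the planted
#'   coupling).
#' @param participant_id Participant label.
#' @return List with `ts` ([bold_timeseries()]), `confounds`, `task`,
#'   `seed_mask`, `cluster_masks`, and the config.
#' @export
generate_timeseries_dataset <- function(cfg = sim_timeseries_config(),
                                        condition = c("Stressor", "Neutral"),
                                        participant_id = "sub01") {
  stopifnot(inherits(cfg, "sim_timeseries_config"))
  condition <- match.arg(condition)
  set.seed(cfg$seed)
  n_runs <- cfg$n_baseline_runs + cfg$n_image_runs
  samp_run <- round(cfg$run_len_s / cfg$tr_s)
  if (abs(samp_run * cfg$tr_s - cfg$run_len_s) > 1e-9)
    stop("run length must be an integer number of TRs")
  nt <- n_runs * samp_run
  dims <- cfg$grid_dims
  nvox <- prod(dims)

  task <- default_task_design(cfg$n_baseline_runs, cfg$n_image_runs,
                              cfg$run_len_s)
  conf <- sim_confounds(nt, cfg$tr_s)
  conf_combo <- (conf$wm + conf$csf + conf$global) / 3

  # evoked regressor over the session
  box <- unlist(lapply(seq_len(n_runs), function(r)
    run_boxcar(task, r, (r - 1) * cfg$run_len_s, samp_run, cfg$tr_s)))
  h <- hrf_double_gamma(cfg$tr_s)
  evoked <- stats::convolve(c(box, numeric(length(h))), rev(h),
                            type = "open")[seq_len(nt)]

  s_lat <- band_limited_signal(nt, cfg$tr_s, cfg$band)
  img_samp <- (cfg$n_baseline_runs * samp_run + 1):nt

  vals <- array(rnorm(nvox * nt, sd = max(cfg$noise_sd, 1e-12)),
                dim = c(dims, nt))
  lin <- function(v) v[, 1] + dims[1] * (v[, 2] - 1) +
    dims[1] * dims[2] * (v[, 3] - 1)

  seed_lin <- lin(cfg$seed_roi)
  flat <- matrix(vals, nvox, nt)
  flat[seed_lin, ] <- rep(s_lat, each = length(seed_lin)) +
    matrix(rnorm(length(seed_lin) * nt, sd = 0.05), length(seed_lin)) +
    cfg$confound_amp * rep(conf_combo, each = length(seed_lin)) +
    cfg$evoked_amp * rep(evoked, each = length(seed_lin))

  cluster_masks <- list()
  cluster_sigs <- list()
  for (ci in seq_along(cfg$target_clusters)) {
    tc <- cfg$target_clusters[[ci]]
    cc <- if (condition == "Stressor") tc$coupling_stress else tc$coupling_neutral
    vlin <- lin(tc$voxels)
    # one distractor shared by the whole cluster: a functional cluster is
    # spatially coherent, and spatial smoothing must not alter the planted
    # seed-cluster correlation
    d_cl <- band_limited_signal(nt, cfg$tr_s, cfg$band)
    sig <- d_cl
    sig[img_samp] <- cc * s_lat[img_samp] + sqrt(1 - cc^2) * d_cl[img_samp]
    cluster_sigs[[ci]] <- sig
    flat[vlin, ] <- rep(sig + cfg$evoked_amp * evoked +
                          cfg$confound_amp * conf_combo,
                        each = length(vlin)) +
      rnorm(length(vlin) * nt, sd = max(cfg$noise_sd, 1e-12))
    m <- array(FALSE, dims)
    m[tc$voxels] <- TRUE
    cluster_masks[[ci]] <- roi_mask(m, sprintf("target%d", ci))
  }
  seed_arr <- array(FALSE, dims)
  seed_arr[cfg$seed_roi] <- TRUE

  # realized (sample) seed-cluster Fisher z per epoch: the planted coupling
  # as it actually materialized in this finite band-limited draw
  ep_samples <- function(runs) unlist(lapply(runs, function(r)
    ((r - 1) * samp_run + 1):(r * samp_run)))
  epoch_runs <- c(list(baseline = seq_len(cfg$n_baseline_runs)),
                  lapply(stats::setNames(seq_len(cfg$n_image_runs %/% 2),
                                         c("early", "mid", "late")[seq_len(cfg$n_image_runs %/% 2)]),
                         function(e) cfg$n_baseline_runs + c(2 * e - 1, 2 * e)))
  truth <- do.call(rbind, lapply(seq_along(cluster_sigs), function(ci) {
    zs <- vapply(epoch_runs, function(runs) {
      idx <- ep_samples(runs)
      atanh(max(min(cor(cluster_sigs[[ci]][idx], s_lat[idx]), 1 - 1e-7),
                -(1 - 1e-7)))
    }, numeric(1))
    data.frame(cluster = ci,
               coupling = if (condition == "Stressor")
                 cfg$target_clusters[[ci]]$coupling_stress
               else cfg$target_clusters[[ci]]$coupling_neutral,
               realized_z = mean(zs[setdiff(names(zs), "baseline")]) -
                 zs[["baseline"]])
  }))

  run_slices <- lapply(seq_len(n_runs), function(r)
    c((r - 1) * samp_run + 1, r * samp_run))
  ts <- bold_timeseries(array(flat, c(dims, nt)), cfg$tr_s, run_slices,
                        condition = condition,
                        participant_id = participant_id,
                        voxel_mm = cfg$voxel_mm)
  list(ts = ts, confounds = conf, task = task,
       seed_mask = roi_mask(seed_arr, "seed"),
       cluster_masks = cluster_masks, cluster_truth = truth, config = cfg)
}

#' Generate a full synthetic study (participants x conditions)
#'
#' Draws one [generate_timeseries_dataset()] acquisition per participant and
#' condition (with per-acquisition seeds derived from `seed`) plus a ratings
#' table, giving everything the group-level pipeline consumes.
#'
#' @param cfg A [sim_timeseries_config()] (its `seed` field is overridden per
#'   acquisition).
#' @param n_participants Number of participants.
#' @param seed Master RNG seed.
#' @param drift Ratings drift passed to [generate_ratings()].
#' @param behavior_link If `TRUE`, the stressor-condition stress and arousal
#'   ratings of the image runs are shifted by `link_gain` times each
#'   participant's realized (sample) baseline-relative seed-cluster Fisher z
#'   for the first target cluster, planting a genuine brain-behavior
#'   association for end-to-end validation.
#' @param link_gain Rating units per z unit of realized network strength.
#' @return List with `acquisitions` (participant -> condition -> dataset),
#'   `ratings`, `truth` (per participant realized z per cluster),
#'   `seed_mask`, `cluster_masks`, and the config.
#' @export
generate_study_dataset <- function(cfg = sim_timeseries_config(),
                                   n_participants = 8, seed = 1, drift = 1,
                                   behavior_link = FALSE, link_gain = 3) {
  ids <- sprintf("sub%02d", seq_len(n_participants))
  acq <- lapply(seq_along(ids), function(i) {
    lapply(c(Stressor = "Stressor", Neutral = "Neutral"), function(cond) {
      cfg_i <- cfg
      cfg_i$seed <- as.integer((seed * 10007L + i * 211L +
                                  (cond == "Neutral") * 101L) %% .Machine$integer.max)
      generate_timeseries_dataset(cfg_i, condition = cond,
                                  participant_id = ids[i])
    })
  })
  names(acq) <- ids
  first <- acq[[1]]$Stressor
  ratings <- generate_ratings(n_participants, first$task, drift = drift,
                              seed = seed + 977L)
  truth <- do.call(rbind, lapply(ids, function(pid) {
    tr <- acq[[pid]]$Stressor$cluster_truth
    tr$participant <- pid
    tr
  }))
  if (behavior_link && length(cfg$target_clusters) > 0) {
    z1 <- truth$realized_z[truth$cluster == 1]
    offset <- round(link_gain * (z1 - mean(z1)))
    names(offset) <- ids
    img_runs <- cfg$n_baseline_runs + seq_len(cfg$n_image_runs)
    sel <- ratings$condition == "Stressor" & ratings$run %in% img_runs
    for (sc in c("stress", "arousal")) {
      v <- ratings[[sc]]
      v[sel] <- v[sel] + offset[ratings$participant[sel]]
      ratings[[sc]] <- pmin(9L, pmax(1L, as.integer(v)))
    }
  }
  list(acquisitions = acq, ratings = ratings, truth = truth,
       seed_mask = first$seed_mask, cluster_masks = first$cluster_masks,
       config = cfg)
}

#' Generate per-run subjective ratings
#'
#' Integer ratings on the 9-point scale for stress, arousal and focus, per
#' participant, condition and run. Stress and arousal start near the scale
#' floor and, in the stressor condition, climb by `drift` per two-run epoch;
#' focus is high and condition-independent. Gaussian noise is discretized by
#' rounding and ratings are clipped to the 1..9 range.
#'
#' @param n_participants Number of participants.
#' @param design A [task_design()] (provides run structure).
#' @param drift Per-epoch increment of stressor-condition stress/arousal.
#' @param seed RNG seed.
#' @param noise_sd Rating noise SD before discretization.
#' @param n_runs Total runs per condition (baseline + image).
#' @return data.frame with columns `participant`, `condition`, `run`,
#'   `stress`, `arousal`, `focus`.
#' @export
generate_ratings <- function(n_participants, design = default_task_design(),
                             drift = 1, seed = 1, noise_sd = 0.5,
                             n_runs = 8) {
  if (!is.finite(drift)) stop("drift must be finite")
  set.seed(seed)
  base_level <- c(stress = 2, arousal = 3, focus = 7)
  rows <- expand.grid(run = seq_len(n_runs),
                      condition = c("Stressor", "Neutral"),
                      participant = sprintf("sub%02d", seq_len(n_participants)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("participant", "condition", "run")]
  # epoch index 0 for baseline runs, 1..3 for image-run epochs
  ep_idx <- pmax(0, ceiling((rows$run - 2) / 2))
  subj_bias <- rnorm(n_participants, sd = 0.5)
  names(subj_bias) <- sprintf("sub%02d", seq_len(n_participants))
  for (scale_name in c("stress", "arousal", "focus")) {
    mu <- base_level[scale_name] + subj_bias[rows$participant]
    if (scale_name != "focus")
      mu <- mu + drift * ep_idx * (rows$condition == "Stressor")
    v <- round(mu + if (noise_sd > 0) rnorm(nrow(rows), sd = noise_sd) else 0)
    rows[[scale_name]] <- pmin(9L, pmax(1L, as.integer(v)))
  }
  rows
}
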