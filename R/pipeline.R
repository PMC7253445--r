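# End-to-end orchestration: connectivity -> clusters -> features -> outcomes
# -> model fitting -> consistency, from a dataset directory on disk.

#' Pipeline configuration
#'
#' Validates and normalizes the configuration consumed by [run_pipeline()].
#'
#' @param data_dir Dataset directory in the layout of [write_sim_dataset()].
#' @param out_dir Output directory.
#' @param seed_mask Path to the seed ROI NIfTI (default
#'   `masks/seed.nii.gz` inside `data_dir`).
#' @param band Passband (Hz).
#' @param fwhm_mm Smoothing FWHM (mm).
#' @param voxel_p,alpha Cluster-forming and cluster-extent thresholds.
#' @param selection_p In-fold selection threshold.
#' @param scheme,k Cross-validation scheme.
#' @param n_perm Permutations for model p-values and the extent threshold.
#' @param outcomes Outcome labels to model.
#' @param reference `"sb"` or `"sbnb"`.
#' @param window `"all"` or `"early"`.
#' @param seed Master RNG seed.
#' @param qc Apply motion run exclusion.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            seed_mask = file.path(data_dir, "masks",
                                                  "seed.nii.gz"),
                            band = c(0.01, 0.1), fwhm_mm = 6,
                            voxel_p = 0.001, alpha = 0.05,
                            selection_p = 0.05, scheme = "loo", k = 10,
                            n_perm = 1000, outcomes = "mean_stress",
                            reference = "sb", window = "all", seed = 1,
                            qc = TRUE) {
  if (!is.numeric(voxel_p) || voxel_p <= 0 || voxel_p >= 1)
    stop("voxel_p must lie in (0, 1)")
  if (!is.numeric(selection_p) || selection_p <= 0 || selection_p >= 1)
    stop("selection_p must lie in (0, 1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  stopifnot(reference %in% c("sb", "sbnb"), window %in% c("all", "early"),
            scheme %in% c("loo", "kfold"))
  if (!dir.exists(data_dir)) stop("data_dir does not exist: ", data_dir)
  if (!file.exists(seed_mask)) stop("seed mask not found: ", seed_mask)
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 seed_mask = seed_mask, band = band, fwhm_mm = fwhm_mm,
                 voxel_p = voxel_p, alpha = alpha, selection_p = selection_p,
                 scheme = scheme, k = k, n_perm = n_perm, outcomes = outcomes,
                 reference = reference, window = window, seed = seed,
                 qc = qc),
            class = "pipeline_config")
}

read_participant_condition <- function(data_dir, pid, cond, voxel_mm, tr_s,
                                       run_len_s) {
  bold <- read_nifti_vol(file.path(data_dir, pid,
                                   paste0(cond, "_bold.nii.gz")))
  nt <- dim(bold)[4]
  samp <- round(run_len_s / tr_s)
  runs <- lapply(seq_len(nt %/% samp), function(r)
    c((r - 1) * samp + 1, r * samp))
  list(ts = bold_timeseries(bold, tr_s, runs, condition = cond,
                            participant_id = pid, voxel_mm = voxel_mm),
       conf = read_confounds_tsv(file.path(data_dir, pid,
                                           paste0(cond, "_confounds.tsv"))),
       task = read_events_tsv(file.path(data_dir, pid,
                                        paste0(cond, "_events.tsv")),
                              run_duration_s = run_len_s))
}

#' Run the full sCPM pipeline on a dataset directory
#'
#' Stages: per-participant background connectivity (confound/task regression,
#' smoothing, bandpass, epoching, seed maps), group cluster definition with
#' permutation extent correction, cluster-mean features, ratings-derived
#' outcomes, cross-validated sCPM fits with permutation p-values, and a
#' linked-shuffle consistency test across the outcome family. All artifacts
#' (clusters, features, outcomes, results, null distributions, config
#' snapshot) are written under `out_dir`; a re-run with the same config and
#' seed reproduces them.
#'
#' @param config A [pipeline_config()] (or a YAML file path of its fields).
#' @return List with the cluster set, feature matrix, outcome vectors, fits
#'   and consistency result (invisibly).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfgl <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfgl)
  }
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- jsonlite::read_json(file.path(config$data_dir, "config.json"),
                              simplifyVector = TRUE)
  vx <- meta$voxel_mm
  tr <- meta$tr_s
  run_len <- meta$run_len_s
  pids <- sort(list.dirs(config$data_dir, recursive = FALSE,
                         full.names = FALSE))
  pids <- setdiff(pids, "masks")
  roi <- read_roi_mask(config$seed_mask, "seed")

  z_maps <- stage("connectivity", {
    lapply(stats::setNames(pids, pids), function(pid) {
      lapply(c(Stressor = "Stressor", Neutral = "Neutral"), function(cond) {
        d <- read_participant_condition(config$data_dir, pid, cond, vx, tr,
                                        run_len)
        bg <- background_connectivity_maps(d$ts, d$conf, d$task, roi,
                                           fwhm_mm = config$fwhm_mm,
                                           band = config$band, qc = config$qc)
        bg$epoch_maps
      })
    })
  })

  clusters <- stage("clusters", {
    diff_list <- lapply(z_maps, function(p) lapply(p, function(cond_maps) {
      eps <- setdiff(names(cond_maps), "baseline")
      lapply(stats::setNames(eps, eps), function(ep)
        differential_map(cond_maps[[ep]], cond_maps$baseline))
    }))
    D <- stack_maps(lapply(diff_list, condition_difference_map))
    ext <- cluster_extent_threshold(D, voxel_p = config$voxel_p,
                                    alpha = config$alpha,
                                    n_perm = max(100, min(config$n_perm, 500)),
                                    seed = config$seed)
    gsm <- group_contrast(D)
    cl <- clusterize(gsm, voxel_p = config$voxel_p, min_size = ext$k)
    write_cluster_set(cl, file.path(config$out_dir, "clusters.nii.gz"),
                      file.path(config$out_dir, "clusters.json"), vx)
    cl
  })
  if (length(clusters$clusters) == 0)
    stop("pipeline stage 'clusters' found no supra-threshold clusters")

  features <- stage("features", {
    f <- cluster_mean_features(z_maps, clusters,
                               reference = config$reference,
                               window = config$window)
    write_feature_tsv(f, file.path(config$out_dir, "features.tsv"))
    f
  })

  ratings <- read.delim(file.path(config$data_dir, "ratings.tsv"))
  outcome_vectors <- stage("outcomes", {
    em <- epoch_rating_means(ratings)
    ov <- lapply(stats::setNames(config$outcomes, config$outcomes),
                 function(lab) relative_outcome(em, lab,
                                                reference = config$reference,
                                                participants = rownames(features)))
    df <- data.frame(participant = rownames(features),
                     do.call(cbind, ov), check.names = FALSE)
    write.table(df, file.path(config$out_dir, "outcomes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ov
  })

  fits <- stage("fit", {
    lapply(stats::setNames(config$outcomes, config$outcomes), function(lab) {
      fit <- scpm_fit(features, outcome_vectors[[lab]],
                      scheme = config$scheme, k = config$k,
                      p_thresh = config$selection_p, n_perm = config$n_perm,
                      seed = config$seed)
      write_scpm_result_json(
        fit, file.path(config$out_dir, sprintf("scpm_%s.json", lab)),
        file.path(config$out_dir, sprintf("scpm_%s_null.tsv", lab)))
      fit
    })
  })

  consistency <- NULL
  if (length(config$outcomes) > 1) {
    consistency <- stage("consistency", {
      fam <- lapply(config$outcomes, function(lab)
        list(features = features, outcome = outcome_vectors[[lab]],
             label = lab))
      cr <- consistency_permutation_test(fam, n_perm = config$n_perm,
                                         seed = config$seed,
                                         p_thresh = config$selection_p,
                                         scheme = config$scheme, k = config$k)
      write.table(cr$table, file.path(config$out_dir, "consistency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      cr
    })
  }
  snap <- unclass(config)
  jsonlite::write_json(snap, file.path(config$out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(clusters = clusters, features = features,
                 outcomes = outcome_vectors, fits = fits,
                 consistency = consistency, config = config))
}
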