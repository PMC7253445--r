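# Outcome vectors from per-run ratings: epoch means, baseline-relative
# values over mean/late windows, and the chronic-stress (PSS) pass-through.

#' Per-epoch rating means
#'
#' Averages each rating scale over the two runs of every epoch, per
#' participant and condition. An epoch with one missing run falls back to
#' the available run (logged); an epoch with no runs is absent.
#'
#' @param ratings data.frame with columns `participant`, `condition`, `run`,
#'   and one or more rating scales (e.g. `stress`, `arousal`, `focus`).
#' @param spec An [epoch_spec()].
#' @return data.frame with columns `participant`, `condition`, `epoch` and
#'   the per-epoch means of each scale.
#' @export
epoch_rating_means <- function(ratings, spec = epoch_spec()) {
  scales <- setdiff(names(ratings), c("participant", "condition", "run"))
  out <- list()
  incomplete <- 0L
  for (pid in unique(ratings$participant)) {
    for (cond in unique(ratings$condition)) {
      sub <- ratings[ratings$participant == pid & ratings$condition == cond, ]
      for (ep in names(spec$mapping)) {
        rows <- sub[sub$run %in% spec$mapping[[ep]], , drop = FALSE]
        if (nrow(rows) == 0) next
        if (nrow(rows) < length(spec$mapping[[ep]])) incomplete <- incomplete + 1L
        rec <- data.frame(participant = pid, condition = cond, epoch = ep,
                          stringsAsFactors = FALSE)
        for (sc in scales) rec[[sc]] <- mean(rows[[sc]])
        out[[length(out) + 1]] <- rec
      }
    }
  }
  if (incomplete > 0)
    message(sprintf("%d epoch(s) averaged from a single available run",
                    incomplete))
  do.call(rbind, out)
}

#' Baseline-relative outcome vector
#'
#' Builds the outcome matched to the sCPM feature reference: the mean window
#' is the unweighted mean of the early/mid/late baseline-relative values, the
#' late window is late minus baseline; with `reference = "sbnb"` the
#' neutral-condition analogue is subtracted. `"pss"` passes the chronic
#' stress score through unchanged.
#'
#' @param epoch_means Output of [epoch_rating_means()].
#' @param label One of `"mean_stress"`, `"late_stress"`, `"mean_arousal"`,
#'   `"late_arousal"`, `"mean_focus"`, `"late_focus"`, `"pss"`.
#' @param reference `"sb"` (stressor minus its baseline) or `"sbnb"`.
#' @param pss Named per-participant PSS scores (required for `"pss"`).
#' @param participants Participant ordering of the result (default: order of
#'   appearance).
#' @return Named numeric outcome vector aligned to `participants`.
#' @export
relative_outcome <- function(epoch_means, label, reference = c("sb", "sbnb"),
                             pss = NULL,
                             participants = unique(epoch_means$participant)) {
  reference <- match.arg(reference)
  if (label == "pss") {
    if (is.null(pss)) stop("pss scores required for label 'pss'")
    missing_ids <- setdiff(participants, names(pss))
    if (length(missing_ids) > 0)
      stop("missing PSS for: ", paste(missing_ids, collapse = ", "))
    return(pss[participants])
  }
  parts <- strsplit(label, "_")[[1]]
  if (length(parts) != 2 || !(parts[1] %in% c("mean", "late")))
    stop("unknown outcome label: ", label)
  window <- parts[1]
  scale_name <- parts[2]
  if (!(scale_name %in% names(epoch_means)))
    stop("unknown rating scale: ", scale_name)
  one_cond <- function(pid, cond) {
    sub <- epoch_means[epoch_means$participant == pid &
                         epoch_means$condition == cond, ]
    val <- function(ep) {
      v <- sub[[scale_name]][sub$epoch == ep]
      if (length(v) == 0) stop(sprintf("missing epoch '%s' for %s/%s",
                                       ep, pid, cond))
      v
    }
    if (window == "late") val("late") - val("baseline")
    else mean(c(val("early"), val("mid"), val("late"))) - val("baseline")
  }
  out <- vapply(participants, function(pid) {
    v <- one_cond(pid, "Stressor")
    if (reference == "sbnb") v <- v - one_cond(pid, "Neutral")
    v
  }, numeric(1))
  names(out) <- participants
  out
}

#' Align an outcome vector to feature-matrix rows
#'
#' @param features Feature matrix with participant rownames.
#' @param outcome Named outcome vector.
#' @return Outcome reordered to the feature rows; errors on mismatch.
#' @export
align_outcome <- function(features, outcome) {
  ids <- rownames(features)
  if (is.null(ids) || is.null(names(outcome)))
    stop("both features and outcome must carry participant ids")
  if (!setequal(ids, names(outcome)))
    stop("participant sets of features and outcome differ")
  outcome[ids]
}
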