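---
title: "Seed connectome-based predictive modeling: models, assumptions and validation"
author: "scpm maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed connectome-based predictive modeling: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a sustained stressor, spontaneous ("background") coupling between a
seed region and the rest of the brain reorganizes, and the strength of that
reorganization differs across people. Seed connectome-based predictive
modeling (sCPM) asks whether those individual differences *predict* a
subjective outcome — e.g. how stressed a person reports feeling — in people
the model has never seen. `scpm` implements the full chain: background
connectivity estimation from multi-run task fMRI, group-level definition of
stressor-modulated clusters, cross-validated network models with
nonparametric inference, and consistency analyses across families of models.

## Background connectivity

Functional connectivity computed on raw task data is contaminated by
stimulus-evoked responses that synchronize regions trivially. The package
therefore works on residuals:

1. **Per-run nuisance + task regression** (`confound_regress()`): ordinary
   least squares of every voxel on an intercept, six rigid-body motion
   parameters, white-matter/CSF/global signals (each with its backward
   temporal derivative, first element zero), one-hot outlier regressors, and
   the stimulus boxcar convolved with a canonical double-gamma HRF (response
   peak 6 s, undershoot peak 16 s, undershoot ratio 1/6; `hrf_double_gamma()`)
   plus its derivative. Rank-deficient designs drop collinear columns with a
   warning. Global signal is computed on unsmoothed data.
2. **Spatial smoothing** (`gaussian_smooth()`, default 6 mm FWHM): a plain
   separable Gaussian with edge-renormalized kernels (constants pass through
   unchanged). This deliberately replaces iterative blur-to-target-FWHM
   schemes: the plain kernel is transparent and testable, at the cost of
   slightly underestimating the final smoothness of already-smooth data.
3. **Zero-phase bandpass** (`bandpass()`, 0.01–0.1 Hz): a 4th-order
   Butterworth applied forward–backward per run with odd-reflection padding
   and steady-state initial conditions. The stimulus presentation rate
   (1 image / 6 s = 0.17 Hz) lies above the passband: a pure 0.17 Hz tone
   retains < 3% of its RMS, a mid-band 0.05 Hz tone > 99%. The passband
   floor subsumes a separate low-frequency drift high-pass.

Runs whose mean framewise displacement (sum of absolute frame-to-frame
translation changes plus 50 mm times rotation changes) exceeds 1.5 mm are
excluded a priori (`qc_exclude_runs()`). This FD convention is a transparent
surrogate for rigid-body RMS displacement measures; the threshold applies to
the same "mean frame-to-frame" quantity.

Cleaned runs are concatenated into four two-run epochs — baseline, early,
mid, late, 132 s each at TR = 1 s — and seed-to-voxel maps are computed per
epoch: the mean seed timeseries is Pearson-correlated with every voxel and
Fisher z-transformed, with |r| clipped at 1 − 1e-7 so maps stay finite and
zero-variance voxels set to z = 0. Image-epoch maps minus the preceding
baseline map give the **differential maps** (S−B), optionally contrasted
against the neutral condition ((S−B) − (N−B)).

## Group cluster definition

Participants' condition differences (stressor minus neutral differential
maps, averaged over epochs) are tested against zero voxelwise with a
one-sample t test (`group_contrast()`; covariates such as sex can be
residualized out first, with degrees of freedom reduced accordingly). This
is a deliberate simplification of a full linear mixed model with condition,
epoch and sex effects: pooling epochs and testing participant-level
differences is statistically defensible, fully specifiable, and exact under
permutation, which the mixed-model fit is not.

Supra-threshold voxels (p < 0.001 two-sided) form clusters under face (NN1)
adjacency, with positive and negative voxels never merged (bi-sided;
`clusterize()`). The minimum cluster extent comes from a sign-flip
permutation null (`cluster_extent_threshold()`): each permutation flips each
participant's difference map with probability 1/2, and k is the smallest
integer for which the null probability of any cluster of size ≥ k is at most
α = 0.05 — an exact family-wise error inversion that replaces
smoothness-based Monte-Carlo cluster simulation and requires no estimate of
the noise autocorrelation. Cluster ids are deterministic (descending size,
ties by lexicographically smallest peak coordinate) so feature columns are
reproducible.

`cluster_mean_features()` then builds the participants × clusters feature
matrix: the mean differential over cluster voxels, averaged over early/mid/
late (window `"all"`) or early only (window `"early"`), under reference
`"sb"` or `"sbnb"`.

## The predictive model

For each cross-validation fold (`scpm_fit()`, leave-one-out by default,
ten-fold as an option):

* every cluster is Spearman-correlated with the outcome over the training
  rows; clusters with two-sided p < 0.05 enter the **positive network**
  (r<sub>s</sub> > 0) or **negative network** (r<sub>s</sub> < 0);
* if nothing passes — typical under permuted outcomes — the **largest-drop
  fallback** ranks |r<sub>s</sub>| strongest to weakest, finds the largest
  gap between successive coefficients, and keeps everything above it;
* a univariate linear model of the outcome on mean network strength is fit
  per network (a combined two-predictor model is also provided) and the
  held-out participant is predicted.

Predictive power is the Spearman correlation of predicted with observed
outcomes. Significance is nonparametric: the outcome is shuffled across
participants, the entire cross-validation (selection inside folds) is
re-run per shuffle, and p = (1 + #{null r<sub>s</sub> ≥ observed}) /
(1 + n<sub>perm</sub>) — the plus-one estimator, one-sided per network,
matching each network's directional claim. With 1000 shuffles the smallest
attainable p is 1/1001 ≈ 0.000999.

Numerical choices worth knowing:

* Selection p-values use the t approximation
  t = r√((n−2)/(1−r²)); equivalently each fold thresholds |r_s| at a fixed
  critical value. This is the convention in CPM codebases and is exactly
  what the permutation null re-runs, so inference is internally consistent.
* Ties: columns are ordered by |r<sub>s</sub>| and gaps compared at 1e-9
  resolution with first-occurrence wins, so exact rational ties in rank
  correlations break deterministically (all-equal coefficients keep only
  the strongest cluster). Constant columns are skipped.
* A fold in which a network receives no clusters predicts the training mean
  (intercept-only); the network is recorded as empty there. This keeps the
  null r<sub>s</sub> defined in every permutation without inventing
  features.
* All randomness (fold assignment, permutations) derives from one integer
  seed recorded in the result.

`partial_spearman()` residualizes rank-transformed variables on covariate
ranks before correlating — used to test whether early-window network
strength predicts later feelings even when accounting for concurrent
feelings, motion or age. `enumerate_model_specs()` spells out the model
family (3 seeds × 2 windows × 2 references = 12 per outcome) and
`bonferroni_alpha(12)` the strict per-model α = 0.0042.
`classify_network_response()` labels how a predictive network moved under
the stressor: a positive-network cluster whose connectivity decreased (or a
negative-network cluster whose connectivity increased) responds consistent
with *attenuating* the outcome; the mirrored pattern is *amplifying*; a
network with less than 75% of its clusters agreeing is *random*. The 75%
consistency bound is a package choice — the trichotomy itself does not come
with a numeric rule.

## Consistency across models

`consistency_permutation_test()` asks whether the same clusters anchor many
models. The statistic per cluster (and network sign — positive- and
negative-network memberships are tested separately) is the number of models
in a family whose *every-fold* network contains it. The null applies one
participant relabeling per iteration simultaneously to every outcome — a
**linked shuffle** that severs all brain–behavior links while preserving the
correlations among outcomes, exactly the dependence structure the family
shares. `seed_overlap()` groups every-fold clusters from different seed ROIs
that share at least one voxel (the overlap threshold is configurable; pure
anatomical overlap has no canonical cutoff).

## The synthetic-data generator

No public dataset accompanies this design, so validation runs on generated
data with planted truth.

*Feature-level* (`generate_feature_dataset()`): features are i.i.d. standard
normal; the outcome is β·mean(positive clusters) − β·mean(negative clusters)
plus N(0, σ²) noise. Defaults mirror the study scale: n = 60 participants,
73 clusters, β = 1, σ = 0.3, with clusters 1–2 positive and 3–4 negative.

*Timeseries-level* (`generate_timeseries_dataset()`): a 24 × 24 × 16 grid of
2 mm voxels, TR 1 s, per condition 2 baseline + 6 image runs of 66 s (5-s
images, 1-s ISI). A latent band-limited signal s(t) — inverse FFT of a white
spectrum restricted to 0.01–0.1 Hz, giving exact spectral confinement — is
shared by the seed voxels. Each target cluster carries
c·s(t) + √(1−c²)·d(t) during image runs (d a cluster-wide independent
band-limited distractor, so the planted in-band correlation with the seed
equals c and spatial smoothing cannot inflate it) and d(t) alone during
baseline; couplings are condition-specific. Task-evoked responses
(boxcar ⊗ HRF), confound components and white noise are superimposed; all
other voxels are pure noise. Ratings (`generate_ratings()`) are discretized
clipped Gaussians on the 9-point scale, with a per-epoch stressor drift;
`generate_study_dataset(behavior_link = TRUE)` shifts stressor-run ratings
by each participant's *realized* (sample) seed-cluster Fisher z, planting a
genuine brain–behavior association.

What the generator does **not** emulate: physiological hemodynamics beyond
the canonical HRF, scanner noise spectra, actual head motion (motion enters
only as confound columns), registration error, or anatomical structure. Passing
tests therefore demonstrate the correctness and calibration of the
*procedure*, not performance on real scanner data.

## Validation experiments and their sizes

All experiments below are run by the test suite and by
`scripts/acceptance.R`; sizes are the package's own validation choices.

* **Oracle equivalence.** The compiled cross-validation engine is checked
  against a from-scratch nested-loop R implementation (exact selection
  agreement, predictions to 1e-10) on dozens of random instances, as are
  Spearman/partial Spearman, the largest-drop rule and the clustering
  (union-find oracle).
* **Type-I calibration.** 500 null feature datasets (β = 0, n = 60,
  73 clusters), 200 shuffles each: the positive-network permutation test is
  the single pre-declared test; its achievable rejection probability at
  α = 0.05 is 10/201 ≈ 4.98%, and the observed fraction must sit inside the
  exact binomial 95% band.
* **Power and recovery.** The planted-validation configuration uses n = 60
  with 16 clusters (2 positive + 2 negative planted): the expected number
  of falsely selected clusters per fold (≈ 5% of 12 null columns ≈ 0.3) then
  stays well below the planted network size, so the experiment measures
  recovery rather than dilution. At the full 73-cluster scale the ~3.5
  false selections per fold dilute a 2-cluster network enough that
  nonparametric p < 0.01 is reached in well under half of replicates — a
  real property of correlation-threshold CPM at that feature-to-signal
  ratio, reported by the acceptance script alongside the validation
  configuration.
* **End-to-end connectivity.** With couplings 0.6/−0.5 planted only in the
  stressor condition, the group contrast recovers clusters at the planted
  voxels, and the group-mean S−B feature lies within 0.15 z of
  atanh(coupling) at n = 60. Per-participant features fluctuate with
  SD ≈ 0.35–0.45 z — a 0.01–0.1 Hz signal observed for 132 s has only
  ~15–25 effective degrees of freedom, so single-subject recovery at ±0.15
  is mathematically impossible; only group aggregates are asserted.
  Evoked-only datasets (equal couplings across conditions, strong evoked
  amplitude) yield no supra-threshold clusters in ≈ 95% of runs, the
  family-wise rate the extent threshold is built to deliver.

## Known limitations

* The group model pools epochs; epoch-resolved fixed effects (and their
  interactions) are out of scope.
* The FD formula and plain Gaussian smoothing intentionally diverge from
  specific preprocessing toolchains; numeric compatibility with them is a
  non-goal.
* Cluster-extent correction is permutation-based; with very few
  participants the sign-flip null is coarse (2^n patterns) and the realized
  family-wise rate can wobble around its nominal level.
* The "528 s total" sometimes quoted for three 132-s image epochs is
  internally inconsistent (3 × 132 = 396 s); the implementation uses 132 s
  per epoch throughout.
* Whether late-window outcomes should subtract the baseline or the early
  epoch is ambiguous in prose descriptions of such designs; the baseline
  epoch is used, matching the connectivity differentials.
* Selection uses two-tailed p-values and the fallback ranks absolute
  coefficients; both are choices where one-tailed/signed readings exist.
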