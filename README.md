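# scpm — seed connectome-based predictive modeling

`scpm` builds cross-validated, permutation-tested models that predict a
subjective outcome (e.g. how stressed a person reports feeling) from
seed-based **background** functional connectivity measured during a
sustained task. It is aimed at cognitive/affective neuroscientists who have
multi-run task fMRI with repeated subjective ratings and want
individual-difference predictions from a hypothesis-driven seed network,
plus the statistical machinery to defend them (nonparametric model p-values,
feature-consistency tests, cross-seed overlap).

## The method

For each participant and condition, trial-evoked responses and confounds
(6 motion parameters, WM/CSF/global signals with temporal derivatives,
outlier spikes, boxcar ⊗ double-gamma HRF) are regressed out per run, the
residuals smoothed (6 mm FWHM) and bandpass-filtered (0.01–0.1 Hz,
zero-phase Butterworth, per run), and runs concatenated into 132-s epochs
(baseline, early, mid, late). Seed-to-voxel Pearson maps per epoch are
Fisher-transformed, z = atanh(r), and image epochs are referenced to the
preceding baseline (S−B, or (S−B)−(N−B) against a neutral condition).
Stressor-modulated clusters come from a voxelwise one-sample t contrast of
condition differences (p < 0.001, bi-sided first-nearest-neighbour
clustering) with a sign-flip permutation cluster-extent threshold at
family-wise α = 0.05.

The seed connectome-based predictive model (sCPM) then runs leave-one-out
(or k-fold) cross-validation. On each training set, clusters whose Spearman
correlation with the outcome has p < 0.05 form a positive
(r<sub>s</sub> > 0) and a negative (r<sub>s</sub> < 0) network — with a
largest-drop fallback when nothing passes — and a linear model of the
outcome on mean network strength predicts the held-out participant.
Predictive power is r<sub>s</sub>(predicted, observed); significance comes
from re-running the entire pipeline on shuffled outcomes,
p = (1 + #{null ≥ observed}) / (1 + n_perm). Clusters selected in **every**
fold feed a linked-shuffle consistency test across model families
(3 seeds × 2 windows × 2 references = 12 models per outcome; strict
Bonferroni 0.05/12 = 0.0042) and a cross-seed anatomical-overlap analysis.

Because no public dataset accompanies this design, the package ships a
synthetic-data module that plants known truth — band-limited seed-coupled
voxel clusters with condition-specific coupling, task-evoked signal,
confounds, and ratings genuinely linked to realized network strength — so
every stage is testable end to end.

## Worked example

```r
library(scpm)

# 60 participants, 16 clusters; clusters 1-2 drive the outcome up,
# clusters 3-4 drive it down (effect 1 z-unit, rating noise SD 0.3)
ds <- generate_feature_dataset(sim_feature_config(
  n_participants = 60, n_clusters = 16, pos_ids = 1:2, neg_ids = 3:4,
  beta = 1, noise_sd = 0.3, seed = 42))

fit <- scpm_fit(ds$features, ds$outcome, n_perm = 1000, seed = 7)
fit
#> <scpm_result> loo CV, n = 60, 16 clusters
#>   predictive r_s: pos 0.683, neg 0.687, combined 0.913
#>   permutation p (1000 shuffles): pos 0.000999, neg 0.000999
#>   every-fold clusters: pos {c1,c2}, neg {c3,c4}
```

The positive-network model predicts held-out outcomes with
r<sub>s</sub> = 0.68, beating all 1000 outcome shuffles
(p = 1/1001 ≈ 0.001); both planted networks are recovered on every
leave-one-out fold, and nothing else is. `bonferroni_alpha(12)` returns the
per-model α of `0.0042` used when all 12 models of a family are tested.

The full NIfTI-in → results-out pipeline (connectivity → clusters →
features → outcomes → fit → consistency) is driven by `run_pipeline()` or
the `exec/scpm` command-line script (`scpm simulate|connectivity|clusters|
features|outcomes|fit|consistency|run`), e.g.

```sh
Rscript exec/scpm simulate --out demo_data --n 8 --seed 1
Rscript exec/scpm run --data demo_data --out demo_results --n-perm 200
```

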