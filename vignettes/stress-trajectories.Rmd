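---
title: "Modeling stress-response trajectories and predicting body mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stress-response trajectories and predicting body mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresstraj)
```

## The problem

Acute psycho-social stress unfolds over minutes: a PreStress phase of easy
arithmetic, a Stress phase with time pressure and negative feedback, and a
PostStress recovery phase, flanked by two resting-state scans. `stresstraj`
models how a person's brain response *trajectory* across this session —
block-wise activation changes in a 21-ROI stress network and block-wise
functional connectivity (FC) between its regions — relates to a continuous
body-mass outcome (BMI, kg/m²), and whether peripheral markers (cytokines,
cortisol) share variance with the brain-predicted part of that outcome or
with the remainder.

The pipeline has five stages, each usable on its own:

1. **Timeseries preparation** — per-segment denoising and rest–task–rest
   concatenation with baseline offset matching.
2. **Trajectory estimation** — one hierarchical regression per ROI pair
   ("edge"), giving partial-pooled per-subject estimates of block
   activation and block FC.
3. **Feature assembly** — aggregation to 180 activation (12 regions × 15
   blocks), 68 connectivity (4 subnetworks × 17 timepoints), or 248
   combined features per subject.
4. **Prediction** — confound-aware nested cross-validated elastic net with
   permutation inference, leave-feature-set-out importance, weight
   stability, and sex-stratified/cross-sex analyses.
5. **Attribution** — decomposition of the outcome into out-of-fold
   prediction plus residual, with marker regressions on each component;
   plus subjective/endocrine/cardiovascular stress markers and
   distribution-matched resampling across sexes.

Because the underlying human data are not publicly deposited, the package
ships a seeded synthetic-cohort generator with exported ground truth, so
every stage is testable end to end.

## Concatenation and offset matching

Each segment is linearly detrended (no quadratic term — a quadratic could
absorb genuine task structure, since the non-stress phases flank the acute
stress), despiked, residualized against nuisance regressors (six motion
parameters, their derivatives, ten physiological components, framewise
displacement), and demeaned. The order detrend → despike → nuisance →
demean is a package choice; the stages are near-commuting on clean data and
the order keeps the despiking threshold interpretable.

Despiking winsorizes samples more than `despike_k = 4` robust deviations
from an 11-sample running median. The rule is deterministic and
parameter-light; both constants are exposed.

Concatenation matches baselines per ROI: the mean over the PreStress
fixation samples of the task segment (all five fixation blocks are used) is
subtracted from the whole task segment, and each flanking resting-state is
shifted to that same (zero) level. Within-segment differences are never
touched, so matching is idempotent. Samples inside task blocks carry one of
15 block labels; rest segments carry `rest1`/`rest2`; fixation and verbal
feedback samples inside the task carry `task_fixation`/`feedback_gap` and
are excluded from block means but retained in the series.

## Per-edge hierarchical models

For each of the 210 unordered ROI pairs (canonical upper-triangle order;
the first ROI is the dependent variable), the concatenated signal is
regressed on an intercept, 17 timepoint regressors (15 task blocks and the
two resting-states), the centered predictor-ROI timeseries, the 17
timepoint × predictor interactions (block-wise FC changes relative to the
baseline coupling), HRF-convolved motor and feedback regressors (canonical
double-gamma response, peaks at 6 s and 16 s, undershoot ratio 1/6 — the
conventional shape, since no parameters are prescribed), and per-segment
linear drift terms that mirror the detrending of the prep stage (without
them, detrending leaves a small systematic bias in block coefficients).

Activation and interaction terms vary by participant. Two engines produce
the partial-pooled per-subject estimates:

* `engine = "mom"` (default): per-subject least squares followed by
  empirical-Bayes shrinkage with DerSimonian–Laird method-of-moments
  variance components, independently per term. This is the default because
  a full mixed model with ~35 random effects per participant is expensive
  at 210 edges and fragile at small cohort sizes, while the two-stage
  estimator is deterministic, fast, and exact in the two limits that
  matter: with a single subject (or noise-free data) it reduces to
  ordinary least squares, and across subjects its estimates always shrink
  toward the group effect.
* `engine = "reml"`: the full linear mixed model with independent
  (diagonal) random effects fitted by REML via `lme4` (maximum likelihood
  fallback on non-convergence). A diagonal covariance is the only stable
  choice at this dimensionality; the two engines agree closely on
  synthetic data and the REML engine serves as the cross-check in the test
  suite.

Aggregation averages each subject's block-activation estimates over all
models in which an ROI is dependent, then over hemispheres, giving 12
regions × 15 task blocks = 180 features. Note one arithmetic subtlety:
under an upper triangle, the last atlas ROI is never dependent. The atlas
therefore orders the three midline ROIs first, so every anatomical
*region* keeps at least one dependent-role model. Only dependent-role
models are used; models where an ROI is merely the predictor do not
contribute to its activation features.

FC features average the interaction estimates within each of four edge
subnetworks for all 17 timepoints (4 × 17 = 68); combined = 248. The
default subnetwork map groups edges by anatomical class (striatal,
limbic-subcortical, hippocampal, cortical/insular); `assign_subnetworks()`
offers a data-driven spectral clustering of group-mean coupling
trajectories for synthetic atlases. The 68 = 4 × 17 factorization is
adopted explicitly: it is the only decomposition consistent with the
feature counts and with trajectories spanning both task blocks and
resting-states, whereas activation features use the 15 task blocks only
(the resting-state coefficients act as reference levels).

## Prediction

`nested_cv_elastic_net()` fixes the elastic-net mixing parameter at
`alpha = 0.5` (a hyperparameter convention for correlated features, not
searched over). Outer folds (default 10) give every subject exactly one
out-of-fold prediction; the penalty is chosen per training fold by inner
cross-validation (default 10 folds, minimum mean squared error over a
100-value log-spaced path). Features are standardized with training-fold
means and SDs only. Confounds — age, sex, diagnosis, pre-task cortisol
responder status, log mean framewise displacement — enter as unpenalized
columns (`penalize_confounds` switches this), and a confound-only ordinary
least-squares baseline is evaluated on the same partition;
`delta_r2 = r2_full − r2_baseline` is the incremental variance explained.
R² is `1 − SS_res/SS_tot` on out-of-fold predictions and may be negative;
it is reported as-is. Predictions cover a narrower range than the outcome
(penalization shrinks toward the training mean) — expected, not an error.

`permutation_test()` permutes (outcome, confounds) rows jointly against the
features, so the confound–outcome correlation survives under the null, and
recomputes the full nested-CV increment per iteration. Each iteration
redraws its fold partition from its own seed stream: reusing one partition
would understate partition variance in the null. The p-value uses the
add-one estimator, so `p >= 1/(B+1)`. Folds are drawn at random without
outcome stratification.

## Outcome decomposition and markers

`prepare_cytokines()` processes a multiplex panel in a fixed order: clip at
detection limits (below-lower → 0, above-upper → upper), drop markers with
more than 16% missing values (strictly), rank-based inverse-normal
transform with plotting position `(rank − 0.5)/n` and midranks for ties
(the constant is documented; any strictly monotone transform of a marker
leaves the result unchanged), per-marker batch residualization, and
per-marker median imputation. Median imputation deliberately replaces a
chained-equations scheme: markers that survive screening have very few
missing cells, so the imputer has almost nothing to do, and a custom
`imputer` hook accepts richer schemes.

`decompose_outcome()` splits observed = predicted + residual exactly;
orthogonality between components is *not* assumed (out-of-fold predictions
need not be uncorrelated with residuals). Markers screened by partial
correlation with the outcome (uncorrected p < 0.05 — a selection step, not
an inference) are regressed on each component with sex, marker × sex, age,
diagnosis, and medication covariates. An association with the predicted
component indicates variance shared with the brain response; association
with only the residual indicates independent variance. The decomposition
uses the all-subject out-of-fold predictions; a female-only retrained model
can be substituted by passing its predictions.

`weighted_resample_match()` evaluates a statistic under male outcome
distributions matched to female moments. The default weights are an
exponential tilt (entropy balancing) calibrated so the weighted mean and
variance equal the reference moments whenever attainable; the simpler
normal-density importance ratio is available as `method = "density_ratio"`
but cannot raise the weighted SD beyond what the group's observed range
supports (with male BMI spanning roughly 19–33, its weighted SD tops out
near 3.4 against a female target of 4.6), which is why it is not the
default. Published cohort moments can be supplied directly via
`reference_moments` instead of being estimated from a finite reference
sample, whose own moments fluctuate across draws.

## Stress markers

Affect sum scores use 5 positive and 10 negative items on a 1–6 scale
(ranges 5–30 and 10–60); deltas are taken against the T3 pre-task baseline
— the methods-level definition — for T6 and T8. Cortisol deltas are
`T6 − T2` and `T8 − T2` (saliva, nmol/l); a pre-task responder is a rise of
*strictly* more than 2.5 nmol/l from T0 to T1. Interbeat intervals outside
0.3–2.4 s are removed; a beat is removed when its relative deviation from
the previous accepted beat, the following beat, and the trailing 50-beat
running mean of accepted beats all exceed an adaptive threshold starting at
13% beat-to-beat change. The adaptation rule — twice the trailing mean
absolute successive relative difference, bounded to [0.13, 0.30] — is a
documented stand-in for an underspecified tool behaviour, exposed via
arguments, and idempotent on its own output. Block heart rate is
`60/mean(IBI)` bpm; phase contrasts compare the five Stress (or PostStress)
blocks with the five PreStress blocks. Association models are
`response ~ BMI × sex + age + diagnosis + responder`, with a Pillai-trace
multivariate test across the four affect deltas (the joint test statistic
is not named in the field's convention; Pillai is the standard robust
choice).

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults encode the reference cohort: 120 females and 70
males; female BMI mean 23.4, SD 4.6, range 17.7–41.9 kg/m²; male mean
24.0, SD 2.8, range 18.9–33.1; 42% mood/anxiety diagnosis; 16% pre-task
cortisol responders; baseline cortisol–BMI correlation −0.27 in females.
Per-sex BMI is drawn by mapping a standard-normal composite score through
the quantile function of a truncated normal whose parameters are
moment-matched so the *post-truncation* mean and SD equal the targets
(naive truncation at the printed ranges would inflate the female mean by
about +0.9 and shrink the SD — the printed moments describe the observed,
bounded sample).

The outcome is built from two independent latent scores per subject: a
brain-linked score that drives the planted trajectory deviations and the
`brain_mediated` markers, and a residual score that drives `independent`
markers. Their variance shares default to 0.30 and 0.40. With
`female_specific = TRUE` (default) the brain share is exactly zero in
males. No published effect sizes link individual trajectory features to
BMI, so the planted magnitudes (default ±1 feature-unit per SD of the
brain-linked score, in the posterior insula, posterior/anterior
hippocampus, and dACC during Stress and PostStress blocks) are free
parameters for recovery experiments, not reproductions. Planted FC effects
default to zero, matching the finding that connectivity did not add
predictive value. Head motion (log mean FD) is carried as a confound of
the prediction interface but left independent of BMI by default
(`fd_bmi_corr`), so recovery of planted effects is identifiable; in real
data the two are correlated, which is exactly why FD is a confound.

Timeseries realize the regression structure the estimator assumes: boxcar
block activation, block-modulated shared latent signals for FC (the
dependent ROI receives `coupling × latent`, the predictor ROI the latent
itself), HRF-convolved auxiliary responses, nuisance leakage, per-segment
drift and intensity offsets, and white noise (`noise_sd = 0.5` signal
units by default). Things the generator does **not** emulate: hemodynamic
convolution of the block response itself (the estimator uses unconvolved
block regressors, so the generator matches), autocorrelated scanner noise,
nonstationary motion artifacts, voxel-level structure, or physiological
waveforms below the IBI level. Passing tests therefore demonstrate
correctness of the estimation and inference machinery under the assumed
generative structure — not robustness to every property of real fMRI data.

`simulate_feature_cohort()` skips timeseries synthesis and adds Gaussian
measurement noise directly to the ground-truth feature matrix. The
prediction, permutation, and attribution studies in the test suite run at
this level (the estimation stage is validated separately by recovery
tests), which keeps the whole suite at desk scale.

## Problem sizes and numerical choices in the checks

The test suite runs: structural counts on a 4-subject full-atlas cohort
with a scaled session (15 blocks of 18 s, 200 task volumes); parameter
recovery at n = 40 on a 6-ROI atlas at default SNR; permutation
calibration on 200 replicate null datasets (n = 100, 20 features,
B = 199, 3 outer/3 inner folds, 10-penalty path — fold counts and path
length are scale choices; permutation validity does not depend on them);
and 20-seed studies for sex-specificity and marker attribution at the
reference cohort size. The acceptance script repeats these computations
from scratch at the same scales with B = 1000 permutations.

Degenerate inputs are handled explicitly: constant outcomes are refused
(R² undefined); collinear nuisance or covariate columns are dropped with a
warning; a sex with fewer than 10 subjects refuses stratified training;
markers that are all-missing or panels that lose every marker raise
errors; IBI blocks with no surviving beats are flagged unusable and
excluded from phase means. Ties in the permutation p-values (a discrete
null with B = 199) are expected and harmless to the calibration check.

## Known limitations

* The two-stage estimator shrinks per term independently; correlated
  random effects are not modeled (nor are they estimable at this
  dimensionality).
* Activation features use dependent-role models only; if an atlas is so
  small that a region loses all dependent-role coverage, aggregation stops
  with a structural error rather than silently switching roles.
* The residual outcome component retains a small share of the brain-linked
  signal because out-of-fold predictions are shrunken; attribution tests
  account for this by testing direction, not exclusivity.
* The IBI threshold-adaptation rule is a documented surrogate for an
  external tool's unpublished behaviour.
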