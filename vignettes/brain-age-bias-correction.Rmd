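---
title: "Modeling and correcting the bias in clinical brain-age predictions"
author: "brainbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting the bias in clinical brain-age predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainbias)
```

## The statistical problem

Brain-age models predict a person's age from a brain MRI; the brain-predicted
age difference (brain-PAD = predicted brain age − chronological age) is a
candidate biomarker. Predictions from such models carry a characteristic
*regression-dilution* bias: young ages are overestimated and old ages
underestimated, so the regression of brain age on chronological age has a
slope below one. Any study that wants unbiased summary statistics of
brain-PAD — or an individual brain-PAD as a personal biomarker — must model
this bias in a sample independent of both the model-training data and the
test data (a *bias-estimation set*) and correct for it.

This package implements that post-prediction machinery: a synthetic cohort
generator standing in for a clinical brain-age dataset, participant-level
stratified splitting, bias-model fitting and cross-validated selection, an
age-independent inverse correction, bootstrap accuracy metrics, slope-removal
tests, mixed-model within-subject comparisons, and reliability statistics.

## The bias model and the two corrections

The bias family is linear in age, in three forms: marginal
(`brain_age ~ age`, 2 coefficients), moderated by modality
(`brain_age ~ age * modality`, one intercept/slope pair per modality), or
moderated by scanner model. Fits are ordinary least squares, or weighted
least squares with weights equal to the inverse frequency of the
observation's modality (or scanner) group, so that each group contributes
equally when group sizes are unbalanced. A level needs at least 3 scans to be
fitted (two parameters plus one residual degree of freedom; levels below that
are flagged unfittable, never silently extrapolated), and a level with zero
age variance is a singular fit and errors.

Given fitted coefficients, two corrections exist:

* **Inverse (age-independent):** `corrected = (brain_age − intercept) / slope`,
  using the record's own level, or — for a level absent from the fit — the
  unweighted mean intercept and slope across fitted levels. Because it never
  reads chronological age it cannot inflate accuracy: the corrected-age/age
  correlation equals the uncorrected one exactly, and
  `var(corrected) = var(uncorrected) / slope²`. Both identities are affine
  facts and are tested at machine precision.
* **Naive (age-dependent):** `corrected = age + brain_age − f(age)`. With
  same-sample coefficients this is `age + OLS residual`, orthogonalized
  against age by construction; with out-of-sample coefficients the
  corrected-age/age correlation still cannot fall below roughly 0.87 *even
  when the predictions carry no age information whatsoever*. The package
  reproduces this inflation in a null simulation and exposes the correction
  only as a diagnostic (`naive_correct()`).

```{r naive-demo}
tab <- list(T2w = list(prevalence = 1, repetitions = c(`1` = 1)))
cfg <- generator_config(n_participants = 1000, modality_table = tab,
                        modality_offsets = c(T2w = 0),
                        modality_noise_sd = c(T2w = 0),
                        failure_modality = NULL, null_mode = TRUE,
                        slice_count = 0, seed = 4)
co <- generate_null_predictions(build_cohort(cfg), cfg)
a <- co[1:500, ]; b <- co[501:1000, ]
fit <- fit_bias_model(a, bias_model_spec("marginal", "OLS"))
c(raw = cor(b$predicted_brain_age, b$age),
  naive = cor(naive_correct(b, fit), b$age))
```

### Cross-validated selection

`select_bias_model_cv()` scores each candidate per fold by fitting it on the
held-out fold's bias subset and computing the bias-corrected MAE on the
fold's evaluation subset, then averages across folds. Mean MAEs are compared
*after rounding to one decimal place*: a model that cannot improve the MAE at
the 0.1-year resolution is not considered better, and ties are broken first
by the smaller coefficient count, then by the smaller across-fold MAE
standard deviation — the simplest, most stable model wins. Candidates that
cannot be fitted in some fold are dropped with a log message.

A practical note discovered in simulation: a modality-moderated model only
wins when between-modality slopes genuinely differ *at comparable
magnitudes*. When one modality's bias slope is near zero (a failed modality),
inverting its per-modality fit divides that modality's noise by a tiny slope
and explodes the corrected error, so cross-validation correctly refuses the
moderated model. This is a feature of the inverse correction, not a defect of
the selection.

## Splitting protocol

Splits are at the participant level — all scans of a participant travel
together — to exclude participant leakage. Stratification uses the Cartesian
product of sex, chronological age binned in 20-year intervals, the
participant's modality set and scanner set; carriers of configured
forced-test modalities/scanners are assigned to the test split first (rare
modalities cannot support training or a stable linear fit), and the remaining
proportions are recomputed over the remainder.

Within each stratum, allocation is largest-remainder apportionment after a
seeded shuffle: each split receives `floor(n_s · p)` members and the leftover
units are drawn (seeded, without replacement) with probabilities proportional
to the fractional remainders. Realized counts are therefore within one
participant of every stratum's targets and unbiased globally; strata smaller
than the number of splits are allocated best-effort and reported via a
warning, never silently.

`check_distributions()` implements the verification protocol: pairwise
two-sample Kolmogorov–Smirnov tests on age and chi-squared tests on sex,
modality and scanner, Bonferroni-corrected across the pairwise comparisons
within each variable. The contract is the protocol (which pairs, which
correction); the tests themselves are the standard `stats` routines.

Observation-weight schemes (`compute_observation_weights()`) cover none,
inverse of the participant's scan count (each participant contributes total
weight 1), and the latter additionally divided by the scan prevalence of the
participant's age bin and sex.

## Accuracy evaluation

Three metrics are reported: MAE, Pearson correlation, and the *constrained*
R² of the model `brain_age = age + error` — residuals against the identity
line but total sum of squares about the mean *prediction*. Unlike the
ordinary R² this can be negative (predictions that poorly follow the
identity line), and it is undefined for constant predictions (reported as
`NA`, never silently zero).

Repeated scans would inflate all three, so they are computed on resamples
drawing participants with replacement and, within each drawn participant, one
repetition uniformly at random. The paper-faithful replicate counts are
`base_reps × N_r` per modality and `base_reps × N_r × N_m` pooled
(`base_reps` 10,000 by default; `N_r` the maximum repetitions, `N_m` the
modality count). Reported are the across-replicate mean and a percentile
interval at level `1 − α/m`, with `m` defaulting to the number of rows of the
emitted table (Bonferroni across the table). Two design choices are worth
stating: participants are resampled with replacement *in addition to* the
repetition draw (without it no confidence interval exists), and intervals are
plain percentile rather than BCa — the simplest choice consistent with the
protocol. Worked examples in the tests pin the scheme to oracles: the
bootstrap mean MAE matches the plain MAE for single-repetition cohorts, and
predictions `age + N(0, σ²)` give MAE ≈ σ·√(2/π).

### Slope-removal tests

`pad_slope_test()` fits `brain-PAD ~ modality × age` by least squares over
all scans, treating scans as independent — exactly the convention implied by
the omnibus degrees of freedom this style of analysis reports — and returns
the omnibus F-test that all modality slopes are zero, per-modality t-tests
(uncorrected, as post-hoc tests), and a contrast on the mean slope over a
caller-chosen modality subset (typically excluding a failure modality). The
repeated-measures caveat is recorded in the returned object: with clustered
scans the omnibus test is anti-conservative, and the residual slope after
correction also inherits the sampling error of the bias-estimation fit, so
small-sample bias sets can leave a small but detectable residual slope.

### Mixed-model within-subject comparisons

`mixed_abs_pad_model()` fits `|brain-PAD| ~ modality + subject + (1|subject)`
by REML and reports each modality's contrast against a reference modality,
Wald confidence intervals (Bonferroni-adjusted across contrasts by default),
a "population" MAE per modality, `MAE-hat_m = mean(s_i) + β_m`, and the
across-modality mean of the latter. Listing subject as both a fixed effect
and a random intercept makes the random-intercept variance only weakly
identified; the model is nevertheless fitted as stated — the estimand is the
within-subject modality contrast, which is unaffected — and all optimizer
messages are captured and reported, never silenced. The residual covariance
is conditionally independent given the subject terms: with subject fixed
effects already absorbing each participant's level, an additional
unstructured within-subject covariance is not identifiable in this design,
so the package does not attempt one. On balanced complete data the contrast
equals the brute-force paired mean difference exactly (an oracle test), and
an all-constant response short-circuits to the degenerate exact answer
(contrasts zero) rather than a meaningless REML fit.

## Reliability

Bias-corrected brain-PADs are reorganized into a participants × items matrix,
the items being modality/repetition pairs (up to 6 modality-sources × 4
repetitions). Dropping rules apply in order: participants with fewer than 3
observed items first, then items missing in more than 95% of the retained
rows — the order matters (the reverse can retain different cells) and follows
the protocol's stated sequence. Cronbach's alpha uses the covariance matrix
under full pairwise deletion (pair-specific means, R's
`use = "pairwise.complete.obs"`); item pairs left with no overlap contribute
zero covariance and are counted in the report. The confidence interval uses
the inverse survival function of the F distribution with
`df1 = rows − 1` and `df2 = df1 × items` ("number of observations" is read as
retained participants). Qualitative bands: ≥ 0.9 excellent, 0.8–0.9
acceptable, ≥ 0.95 redundant — redundancy across modalities being desirable
here.

`within_subject_mad()` is the companion statistic: each participant's mean
absolute deviation of brain-PAD about their own mean, averaged across
participants with a bootstrap CI over participants. Participant-level offsets
cancel by construction, so the measure isolates scan-to-scan consistency; on
the generator this converges to the folded-normal mean of the corrected scan
noise, independent of the subject-effect SD (a property test).

## The synthetic cohort generator

The generator emulates the statistical structure of a clinical brain-age
cohort; it is first-class, tested code, not a test fixture.

* **Ages** are truncated-normal on 15–95 years with underlying location and
  scale calibrated numerically (closed-form truncated moments, Nelder–Mead
  then BFGS on the squared moment error, residual tolerance 10⁻⁶) so that the
  *truncated* mean and SD equal 53.5 and 18 years; the near-symmetric family
  puts the median (56 in the reference cohort) close to the mean, and a
  quadrature oracle verifies the calibration. Unattainable targets raise an
  explicit calibration error. A zero target SD degenerates to a point mass.
* **Composition**: 1540 participants, sex ratio 1039 F / 501 M; each of 7
  modalities is carried with a configured prevalence and, when carried, a
  repetition count in 1–4. The defaults reproduce the reference scan table
  where it is unambiguous (MPRAGE 940 scans; T2w 2221; T2wFLAIR 1009; IR 154,
  all on one scanner; column totals over 8 scanners summing to 6281 scans)
  and allocate the remainder across T1w, T1wFLAIR and T2wGRE consistently
  with those totals. Scanner assignment is marginal per modality, with the
  two never-trained scanner models concentrated on the rare modalities that
  co-occur with them; a fully marginal single table can be configured
  instead. The joint modality × scanner × repetition structure of the real
  archive is *not* reproduced — only these marginals are.
* **Predictions** follow
  `intercept + slope·age + modality_offset + subject_effect + scan_noise`
  with the generating bias defaulting to intercept 15.2 years and slope 0.7.
  The subject effect (SD 3 y) is shared across all of a participant's scans
  and is what drives internal consistency and the mixed model; scan noise is
  modality-specific (5–8 y). One modality (the T2wGRE analog) can be given
  its own gross miscalibration — default intercept 55 y, slope 0.1, noise
  8 y, chosen once to reproduce the qualitative failure signature (huge
  |PAD|, strongly nonzero PAD-age slope) since no generating values exist to
  copy.
* **Slices**: with `slice_count > 0` (default 80) each scan emits per-slice
  predictions equal to the scan value plus i.i.d. Gaussian slice noise
  (SD 4 y; no slice-level error structure is documented anywhere, so
  i.i.d. is the minimal assumption), and the scan-level prediction is the
  *median* across slices, computed by `aggregate_slices()`.
* **Null mode** produces predictions from an honestly fitted but
  uninformative learner: OLS of age on 10 pure-noise features, trained on a
  separate draw and evaluated on fresh noise. The predictions are
  asymptotically uncorrelated with age yet have the reduced variance of a
  fitted learner (≈ p/n times the age variance) — precisely the regime in
  which the naive correction's inflation is demonstrated.
* **Seeds**: one master seed per config; every stage (ages, cohort,
  predictions, each bootstrap, each split) derives its own child stream from
  a string-hashed label, so identical configurations are byte-identical and
  enlarging one stage never perturbs another.

### What passing tests do and do not show

The generator is additive and Gaussian. Real CNN predictions have heavy
tails, age-dependent heteroscedasticity, site effects and quality-control
failures, and their between-modality errors correlate through the shared
image content rather than through a single additive subject effect. Two
consequences deserve emphasis: (i) reliability statistics on the synthetic
defaults (alpha ≈ 0.5–0.8) sit below the excellent-to-redundant range
reported for real data, because independent scan noise at 5–8 years
dominates the 3-year shared subject effect; (ii) parameter-recovery results
here validate the *machinery* — unbiasedness of the fits, correctness of the
correction, calibration of the protocol — not the behavior of any particular
brain-age model on clinical data.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to make Monte-Carlo error
negligible relative to the tested effect while keeping the default suite
fast: 200 replicates for bias-parameter recovery (at the bias-estimation-set
size of 186 participants / ~841 scans) and for the null-inflation bound; 100
seeds for partition properties; 50 replicates per scenario for the
cross-validated selection rates; 10⁵ draws for the age-moment calibration.
Bootstrap tests run at a few hundred base replicates — the scheme is
identical at any `base_reps`, and the paper-faithful default of 10,000
remains the package default.

Other numerical decisions, each made once: the CV tie threshold is one
decimal place of MAE; unseen-level correction averages coefficients
unweighted across fitted levels; the per-level fitting minimum is 3 scans;
apportionment leftovers are drawn proportionally to fractional remainders;
zero-variance responses in the mixed model short-circuit to the exact
degenerate answer; constant predictions make the constrained R² `NA` with a
warning.

## Limitations

* The mixed model follows its stated specification including the
  questionable subject fixed-effect/random-intercept duplication; users
  wanting a conventional specification can drop the fixed subject term
  outside this package.
* The slope tests treat scans as independent by protocol; their p-values are
  anti-conservative under within-participant clustering, and the returned
  object says so.
* The exact joint modality × scanner composition of a real clinical archive
  is not emulated, only its marginals; distribution checks and forced-test
  behavior on real data may differ accordingly.
* No image-level functionality exists or is planned: inputs are tabular
  per-scan predictions (CSV), not MRIs.
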