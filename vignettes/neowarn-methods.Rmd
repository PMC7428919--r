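---
title: "Methods: early-warning modelling of late-onset neonatal sepsis from vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-warning modelling of late-onset neonatal sepsis from vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Late-onset neonatal sepsis (LONS) — sepsis with onset between 72 hours and 120
days after birth — remains a leading cause of morbidity in neonatal intensive
care. Blood culture, the confirmatory test, takes days; empirical antibiotics
are started on clinical suspicion. An early-warning model that flags incipient
sepsis up to 48 hours before the clinical diagnosis, using only the
noninvasive vital signs already charted at the bedside (heart rate,
respiratory rate, oxygen saturation, systolic/mean/diastolic blood pressure,
body temperature), would be deployable in any unit without laboratory or
waveform infrastructure.

`neowarn` implements that modelling pipeline end to end on MIMIC-III-shaped
electronic-medical-record event tables:

1. **Cohort phenotyping** from ICD-9-CM discharge codes (038*, 771*, 995.9*,
   785.52 identify the sepsis group).
2. **Onset dating** from the coincidence of a blood-culture order
   (`SPEC_TYPE_DESC = "BLOOD CULTURE"`) and an intravenous broad-spectrum
   antibiotic start (`ROUTE = "IV"`), because the diagnosis table itself
   carries no timing.
3. **Windowed statistical features** of each vital over 3/6/12/24-hour
   observation windows.
4. **A wrapper forward feature selection** maximizing
   `F = AUROC + average precision` of a Gaussian naive Bayes base model.
5. **Training-set-only resampling** options for the extreme class imbalance.
6. **A leakage-audited evaluation harness** with stratified patient-level
   splits, 10-fold cross-validation, and percentile bootstrap 95% intervals.

Because the real MIMIC-III database is credentialed, the package ships a
**synthetic cohort generator** that emulates the table schemas and plants a
known deterioration signature, so that every downstream stage is testable
with known ground truth. All empirical statements in this vignette are
computed by the package's test suite or by `scripts/acceptance.R`; nothing
here reports numbers from any external dataset.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` simulate demographics, irregular
vital-sign charts, and group-consistent diagnosis, microbiology and
prescription events.

**Population.** Gestational age is drawn from group-conditioned truncated
normals centred at the published NICU cohort medians (30 weeks for the
clinical-LONS group, 34 for controls; spread from the reported interquartile
ranges). Birth weight follows a log-linear model in gestational age through
the group medians (0.80 kg / 2.02 kg). Length of stay is lognormal with
medians 87.9 days (LONS) and 13.3 days (controls). The modelling default
prevalence is 5%; the real-cohort clinical prevalence (21/2798 ≈ 0.75%) is a
configuration choice away, but at desk scale it leaves too few positive
patients for stable fold stratification.

**Charting model.** Each vital is charted at a mean cadence of 60 minutes
(jitter 30%, 10% missingness) — hourly charting is typical NICU practice.
Baselines are gestational-age-conditioned (mean arterial pressure ≈ GA in
mmHg, the standard rule of thumb; heart rate ≈ 155 − 1.2·(GA−30) bpm, and so
on), with between-patient baseline SDs (e.g. 8 bpm for heart rate) and a
per-patient lognormal scale (sdlog 0.25) on the observation noise, because
charting variability genuinely differs between infants.

**Deterioration signature.** Sepsis patients receive, over a pre-onset ramp:
a linear additive drift reaching full size at onset (tachycardia +20 bpm,
respiratory rate +5, blood pressures −8 mmHg, SpO2 −1%), a constant
observation-noise inflation across the ramp (SpO2 ×1.5, temperature ×1.5,
heart/respiratory rate ×1.15, blood pressures ×1.2), and transient
desaturation dips (mean depth 4%, per-observation probability ramping to
0.25). These effect sizes are configurable assumptions, not published facts:
the source cohort study reports only the qualitative signs (tachycardia,
desaturation with widened SpO2 swings, temperature instability,
blood-pressure excursions). They were calibrated once so that the default
48-h-ahead task is learnable but not saturated (target AUROC band
0.85–0.95), mirroring the difficulty reported on real data, and were not
revisited afterwards.

**Ramp length (default 96 h).** The labeled onset is the time clinicians
*reacted* (culture + antibiotics); physiological deterioration precedes it.
If the planted signature were confined to the final 48 h, the prediction
instance at `onset − 48 h` would see a window containing no signal at all and
48-h-ahead prediction would be impossible by construction — contradicting the
method's own premise that such prediction works on real data. The default
ramp therefore spans 96 h before the event-dated onset; `ramp_h` is a single
configurable parameter and `inject_deterioration()` honours whatever value it
is given (observations before `onset − ramp_h` are never modified).

**What the generator does not emulate.** Autocorrelated within-patient noise,
circadian rhythm, care-event artefacts (handling, ventilation changes),
informative sampling (sicker infants charted more often), and co-morbidities.
Passing the package's recovery tests therefore demonstrates the pipeline's
correctness and its ability to find a planted multivariate signature under
irregular sampling, imbalance and missingness — not clinical performance on
real infants.

## Onset labeling

The default `onset_policy()` pairs each blood-culture time with the nearest
IV broad-spectrum antibiotic start within 24 hours, and dates the onset as
the minimum of the earliest valid pair (`earliest_of_pair`), the most
conservative (earliest plausible) choice; `culture_time` and
`antibiotic_time` rules are available. The broad-spectrum drug list is a
configurable set of name patterns (vancomycin, gentamicin, ampicillin,
cefotaxime, ceftazidime, meropenem, piperacillin, amikacin, cefepime,
oxacillin) — the source study never enumerates its list. The LONS window
[72 h, 120 d] is applied with inclusive boundaries (the definition does not
state open/closed; inclusivity keeps the boundary cases).

Sepsis-coded patients whose onset cannot be dated from events are labeled
`proven_sepsis` and excluded from modelling (they are neither clean positives
nor clean negatives); sepsis-coded patients never enter the negative pool, to
avoid label noise near undocumented onsets.

**Instances.** The prediction task takes one positive instance per LONS
patient at `onset − 48 h`; the detection task takes positives every 24 h over
`[onset − 48 h, onset]`. Negatives come from control stays at a 24-hour
cadence, starting once 72 h of age and a full observation window of history
are available. No instance may use data after its own reference time.

## Feature engineering

Thirteen statistics (mean, median, min, max, SD, skewness, kurtosis, slope,
entropy, delta, absolute delta, correlation, cross-correlation) are computed
per vital over half-open windows `(t − w, t]`, for `w` in {3, 6, 12, 24} h
(the default experiment grid uses 6/12/24). Compound features apply the nine
series statistics to the successive-difference (`delta`) and absolute-
difference (`absolute_delta`) series — 31 candidate specs per vital, 217 in
total.

Numerical conventions, chosen where the method description is silent:

* SD uses the n−1 denominator; skewness is the moment coefficient
  g1 = m3/m2^1.5 and kurtosis the excess g2 = m4/m2² − 3 (the conventions of
  the common scientific-Python stack the original analysis used).
* The scalar `delta` is last minus second-to-last observation; the
  delta *transforms* are full difference series (this is the only reading
  consistent with reported compound names like "median absolute delta").
* Univariate statistics are computed on the raw irregular samples; the two
  association statistics on a 15-minute LOCF grid (carrying the last
  observation forward from the full pre-reference history — no look-ahead).
  Each vital is paired with heart rate as the reference signal; heart rate
  pairs with oxygen saturation. Cross-correlation scans lags up to half the
  window, both directions, and returns the value of largest magnitude with
  sign preserved (ties to the smallest, then positive, lag).
* Normality gating uses Shapiro-Wilk below 5000 samples and
  Kolmogorov-Smirnov (moment-estimated parameters) at or above it, at the
  0.05 level. It selects Pearson vs Spearman correlation, and the
  closed-form Gaussian entropy ½·ln(2πes²) vs a plug-in Gaussian-KDE entropy
  (Silverman bandwidth; exact evaluation up to 256 points, a 512-point
  binned grid above).
* Quality control: per-patient three-sigma outlier removal (series with
  fewer than 3 points pass unchanged); cells whose computation is undefined
  (too few points, zero variance) are zero-imputed, as are never-measured
  windows, with a provenance mask distinguishing the two.

## Forward feature selection

For each vital independently, a greedy loop adds up to `k = 3` specs (the
reported selection size per vital), each step choosing the candidate that
maximizes the mean 5-fold stratified cross-validated
`F = AUROC + average precision` of a Gaussian naive Bayes model on the
selected set so far, stopping early when no candidate improves F. The F trace
is non-decreasing by construction. Ties break toward the canonical spec
ordering. AUROC is the pairwise-concordance (rank-sum) form with ties at ½;
average precision the step-wise precision-recall integral with tied scores
grouped.

Because the naive-Bayes log-likelihood is additive across features, the
per-fold per-feature log-likelihood ratios are precomputed once and each
candidate subset is scored with a single row sum — the rankings are
identical to refitting the model per subset, which the test suite verifies
against an exhaustive brute-force oracle at k = 1.

Comparators (all returning the top 21 = 7×3 specs): chi-squared on min-max
scaled features; k-nearest-neighbour mutual information (k = 3, the
Ross-style continuous/discrete estimator); lasso-L1 logistic coefficients
(λ = 1/n, standardized); and impurity/gain importances of extremely
randomized trees, random forest, and gradient boosting. The baseline feature
set is mean/min/max/SD/median per vital (35 specs, no selection).

## Imbalance resampling

SMOTE, random over/under-sampling, NearMiss-1 (mean distance to the 3
nearest minority rows), Wilson's ENN (k = 3, majority edited), Tomek-link
removal (majority member), AllKNN (ENN repeated for k = 1..3), ADASYN
(density-proportional SMOTE allocation), instance-hardness thresholding
(5-fold cross-validated Gaussian-NB probabilities), SMOTEENN and SMOTETomek
compositions. Defaults: 1:1 target ratio, 5 SMOTE neighbours. All are
deterministic under a seed and refuse to run on a partition flagged as test —
the harness relies on that contract for its leakage audit. Resampling is off
(`"none"`) in the default experiment, matching the primary analysis design.

## Evaluation harness

Patients are split 20% (feature selection) / 80% (model evaluation) by a
stratified shuffle at the patient level — the evaluation-diagram fractions;
the alternative 10/80/10 text description is available via `split_plan()`.
The model set is cross-validated with stratified *patient-disjoint* 10-fold
splits; each fold re-instantiates its classifier with default
hyperparameters (no tuning anywhere), applies any resampling to the training
fold only, and scores the untouched validation fold. Out-of-fold predictions
are pooled ("microaverage") and 95% intervals come from a 100-turn
percentile bootstrap over evaluation instances (single-class resamples are
redrawn). Weighted-F1 is the class-frequency-weighted per-class F1; macro-F1
is also computed and exposed, since the two names are used interchangeably
in the field's tables.

Nine classifiers: L2-regularized logistic regression (warm-started ridge
path evaluated at λ = max(1/n, path minimum) — regularized logistic is the
common library default, keeps coefficients finite under separation, and the
path fit is the numerically reliable route to a small penalty), Gaussian
naive Bayes (internal vectorized
implementation, cross-checked against `e1071::naiveBayes` in the tests),
CART decision tree, gradient boosting (xgboost, 100 × depth-3 × η 0.1),
SAMME AdaBoost (50 stumps), bagged CART (25 bags), random forest and
extremely randomized trees (ranger, 300 trees), and a single-hidden-layer
perceptron (nnet, 16 units, L2 decay 1e-4, standardized inputs).

The leakage audit is an explicit collector threaded through the harness:
selection/model patient disjointness, fold disjointness, and the
training-only resampling contract are asserted at run time and counted in
the report.

## Problem sizes and numerical choices in the test suite

The statistic oracle suite uses 1000 random windows per statistic at
tolerance 1e-9 (relative); entropy limits are checked at n = 5000 (closed
form within 0.05 of ½·ln(2πeσ²); uniform KDE entropy within 0.1 of 0).
Planted-feature recovery uses twenty 220-patient cohorts (prevalence 18%,
detection task at 12-hour instance cadence, univariate candidate set) with
deterioration confined to heart-rate drift and SpO2 noise inflation; the
positive-instance count is sized so the selector can resolve the planted
location statistic (mean) from its statistic twins (median, slope) rather
than merely detect the deteriorating vital. The end-to-end study uses the default 2000-patient, 5%
prevalence cohort for the cross-validated AUROC check and ten seeded
cohorts for the window-ordering comparison (24 h ≥ 12 h ≥ 6 h in mean
selection objective F). Bootstrap coverage is studied at 500+500 instances
with 300 turns and 200 outer replications, where the percentile interval's
asymptotics hold (at much smaller n the percentile bootstrap is known to
undercover slightly).

## Known limitations

* The generator's effect sizes are assumptions; recovery results say nothing
  about real-world discriminative performance.
* The onset-combination rule, antibiotic list, negative-instance cadence,
  association pairing and several statistic conventions are documented
  choices where the method description is silent; all are configurable.
* Correlation/cross-correlation features carry little signal at charting
  resolution (they are computed on heavily LOCF-smoothed grids); they are
  included for completeness of the candidate set.
* The detection-task positive cadence (24 h over the final 48 h) is one
  reading of "0–48 h before onset"; others are possible.
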