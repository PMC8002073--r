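---
title: "Methods: longitudinal telomere and chromosome-aberration analysis for radiotherapy cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal telomere and chromosome-aberration analysis for radiotherapy cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloRT)
library(dplyr)
```

## The problem

Radiotherapy patients differ widely in how their telomeres respond to
treatment. Because short telomeres mark risk for degenerative late effects
and long telomeres mark risk for proliferative ones (notably secondary
cancers), a patient's *post*-therapy telomeric state is a candidate
biomarker for individual risk — and predicting it from *pre*-therapy
measurements would let that risk be assessed before treatment begins.

teloRT implements the full analysis chain for this question on
Telo-FISH-style data: thousands of individual telomere relative fluorescence
intensities (RFI, arbitrary units) per blood sample, collected at four
points — pre-therapy non-irradiated (0 Gy), pre-therapy irradiated in vitro
(4 Gy, a proxy for intrinsic radiosensitivity), immediately post-therapy,
and 3 months post-therapy — together with per-cell chromosome aberration
scores from directional genomic hybridization (dGH). Every stage is driven
by a seeded synthetic cohort generator so the whole chain is testable with
known ground truth.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the cohort structure the
analysis assumes:

* 15 patients x 4 time points; 50 metaphase cells x 92 telomere signals =
  4600 measurements per sample (92 = 46 chromosomes x 2 termini, with
  sister-chromatid signals merged — the value forced by 4600 / 50 cells);
  one patient (ID 13) whose 3-month sample fails to culture, leaving 59
  samples and 14 complete patients.
* Two planted response groups: 3 patients whose mean telomere length (MTL)
  falls after therapy and 11 whose rises. Group membership is tied to the
  patient random effect so that shorteners start with relatively longer
  telomeres, matching the observed cohort structure.
* Individual telomere intensities are gamma distributed (right-skewed, as
  observed RFI distributions are). The distribution *family* is a
  configuration choice, not a claim: nothing downstream depends on it
  beyond skewness and positivity. A patient's location at a time point is
  `base_location x group_baseline_shift x patient_effect x
  group_timepoint_multiplier x sample_jitter`, with lognormal patient
  effects (sdlog 0.08) and per-sample jitter (sdlog 0.03). The default
  gamma shape 8 gives a within-patient coefficient of variation of ~35%,
  a realistic width for Q-FISH-style distributions.
* Group time-point multipliers default to (1.00, 1.05, 0.80, 0.70) for
  shorteners and (1.00, 1.10, 1.25, 1.30) for lengtheners: a modest rise
  after 4 Gy in vitro for everyone, then persistent divergence post-therapy.
  These are multiplicative location shifts — the simplest model that
  reproduces two-direction trajectories while leaving distribution shape
  intact.
* Measurement artefacts: a `missing_rate` (default 2%) of values is
  dropped; an `outlier_rate` (default 0.2%) is replaced by values 4–7 bulk
  SDs above the mean. Together with the gamma tail this keeps the fraction
  caught by the 3-SD filter below 1%.
* Batch structure: each patient's raw values carry a lognormal batch effect
  shared with that patient's pair of control lines (a normal and an
  immortalized fibroblast line), so control-based standardization can
  remove it exactly.
* Chromosome aberrations: per-cell counts are Poisson per type, 30 cells
  per sample, with per-patient lognormal rate multipliers (sdlog 0.2) and
  rates per time point that keep inversions the most frequent
  radiation-induced type at irradiated time points. A `clonal_fraction`
  (default 0.1) of aberrations copies the *signature* of an earlier
  aberration in the same patient x time point — identity, not count — so
  clonality correction has work to do while raw counts remain Poisson.
* Blood counts: lymphocytes are negatively coupled to each patient's
  relative MTL change (apparent MTL elevation co-occurring with cell
  killing), with mild shifts in lymphocyte subsets.

One global seed expands into independent per-(patient, time point, stream)
sub-seeds, so regenerating with the same configuration is byte-identical
and adding patients never perturbs existing patients' draws.

What the generator does *not* emulate: imaging artefacts beyond symmetric
value dropout, cell-to-cell correlation of telomere intensities within a
metaphase, per-chromosome telomere identity, time-varying batch effects,
or any coupling between telomere and aberration outcomes. Tests passing on
this cohort therefore validate the *machinery* — bookkeeping, statistics,
splitting, leakage guards, learnability under stated noise — not the
biological effect sizes of any real cohort.

## Processing individual telomere measurements

The pipeline order is fixed: **standardize → remove outliers → impute**.

* *Standardization*: each batch's control pair yields
  `ratio = mean(reference_normal / batch_normal, reference_immortal /
  batch_immortal)`; patient values are multiplied by it. The exact ratio
  convention in the literature this emulates is not fully specified, so the
  convention is the package's documented choice (and the mean-of-ratios
  form is exposed in one place, `compute_control_ratio()`). Standardizing
  *first* keeps the 3-SD outlier rule batch-independent.
* *Outlier removal* (`remove_outliers()`): a single pass dropping values
  more than 3 sample SDs from the sample mean, both computed once from the
  input. The filter is deliberately not iterated: the criterion is stated
  once, and iterating removes well over 1% on heavy-tailed data.
* *Imputation* (`impute_to_theoretical()`): samples below the theoretical
  4600 are topped up by resampling the observed values **with
  replacement** (missing counts may exceed unique values), flagged
  `imputed`. After imputation every sample has exactly 4600 values.
* SDs use the n−1 denominator throughout.

## Quartile feature engineering

`baseline_cutoffs()` takes the 25th/75th percentiles of each patient's
pre-therapy non-irradiated distribution (linear interpolation between order
statistics, the common default; the convention is a parameter). The
cut-offs are computed **once per patient** and reapplied at all four time
points: `count_length_classes()` counts values strictly below q25 as
short, strictly above q75 as long, boundary ties to the middle class —
conservative and deterministic. Counts always sum to the sample size.

A corollary worth knowing: against its *own* cut-offs, a baseline sample of
distinct values has almost exactly 25% / 50% / 25% in the three classes.
Baseline short/long counts are therefore nearly constant across patients,
and a regression using only them is rank-deficient by construction; the
analysis drivers report this as `NA` rather than a number.

## Cohort statistics

* `repeated_measures_anova()` is the one-within-factor repeated-measures
  ANOVA on a complete patients x time points matrix, with the subject x
  time interaction as error term, computed in closed form for speed (the
  calibration suite runs 1000 replicates); it is algebraically identical
  to `aov(y ~ timepoint + patient)`, which the tests use as an independent
  oracle. Tukey HSD p-values come from the studentized range distribution
  on the same error term. Short/long counts are square-root transformed
  (variance stabilization for counts) before testing.
* `cluster_patients()` z-scores each patient's trajectory (so clustering
  sees shape, not level — and is invariant to per-row affine transforms),
  uses `1 − Pearson r` distance (signed, not `1 − |r|`: anti-correlated
  trajectories are *opposite* responses, not similar ones), single-linkage,
  cut at k = 2. k is fixed at 2 for the replication pipeline because the
  emulated cohort contains exactly two response groups per metric; it is a
  parameter. Patients with any missing time point are excluded listwise
  (n = 14 in the default design). Zero-variance rows are an error, not
  silently perturbed.
* `baseline_linear_prediction()` fits the OLS baselines (3-month outcome on
  the baseline metric, or baseline + 4 Gy metrics) and reports in-sample
  r², matching how such baselines are conventionally quoted.
* `longitudinal_correlation()` pools patient x time point pairs and reports
  signed Pearson r and r² separately — never a signed value labelled r².

## Boosted-tree prediction of 3-month outcomes

`build_long_dataset()` reshapes the two processed pre-therapy samples into
one row per individual telomere: value, origin label (0 = non-irradiated,
1 = 4 Gy), patient, and the patient's single 3-month outcome (one model per
outcome: MTL, n_short, n_long). 14 complete patients give 128,800 rows.

* `stratified_shuffle_split()` shuffles and splits 80/20 *within each
  patient x origin stratum* (round half up, residual rows to training),
  then reshuffles globally: 103,040 / 25,760 rows. This guarantees the
  per-stratum balance the design calls for, rather than achieving it only
  in expectation.
* `fit_boosted_regressor()` trains gradient-boosted regression trees
  (squared-error objective) via xgboost, single-threaded and seeded for
  determinism. Features are the telomere value and origin label only;
  passing `patient_id` as a feature is a hard error (leakage guard).
  Presets: 200 trees / depth 7 / learning rate 0.2 / seed 1 for MTL;
  depth 6 for the count outcomes; 200 / depth 15 / 0.1 / seed 0 for the
  per-cell aberration models.
* `cross_validate_mae()` reports per-fold held-out MAE over k = 5 shuffled
  folds. Folds are simple partitions, not patient-stratified — with ~7,360
  rows per patient in training, every fold contains every patient either
  way.
* `evaluate_predictions()` reports MAE, row-level r², and the headline
  metric: per-patient-averaged r² (each patient's predictions averaged
  before comparison with their single true outcome).
* `leave_patients_out()` makes the generalizability claim honest: after one
  global stratified split, each iteration removes whole patients from
  training and moves *all* their rows into the evaluation set. For
  k_out = 1 that is one iteration per patient (14); for k_out > 1 patients
  are partitioned, after a seeded shuffle, into disjoint groups — the
  emulated study does not enumerate its leave-two/three-out combinations,
  so disjoint coverage of every patient is this package's choice.
* `random_hyperparameter_search()` draws configurations uniformly from a
  candidate space and returns the one with the best cross-validated MAE,
  deterministic given its seed.

### What "learnable" means here

Per-row boosted trees can only map (value, origin) → outcome. Their
per-patient accuracy depends on how much a single telomere value says about
which patient it came from, i.e. on the ratio of between-patient location
spread to within-patient distribution width. The default cohort (CV ~35%)
deliberately leaves heavy overlap; there the models land at modest
per-patient r² — the machinery works but the planted signal is partly
washed out at the level of single measurements, which is itself an honest
property of this class of model.

`ml_recovery_config()` encodes the low-noise regime used by the recovery
suites: gamma shape 1000 (CV ~3%), per-sample jitter 0.005, no missingness
or injected outliers. There the 3-month outcome is a near-deterministic
smooth function of baseline location and 4 Gy shift, and the boosted models
reach per-patient test r² ≈ 0.97 with leave-one-patient-out median r² ≈
0.97 — realizing the invariant that per-patient r² → 1 as generative noise
→ 0. During development this configuration was finalized at shape 1000
after a first candidate (shape 200, CV 7%) proved not yet to be in the
asymptotic regime (r² ≈ 0.78, attenuated by residual between-patient
overlap); the default cohort's parameters are independent of this and were
never adjusted.

## Chromosome aberrations

* `parse_score_sheet()` reads per-cell CSVs (one row per metaphase:
  inversions, translocations, dicentrics, excess fragments, SCE, optional
  semicolon-delimited `type:label` signatures) with row-numbered
  diagnostics for malformed input, and normalises score-sheet time-point
  aliases ("1 non irrad", "2 irrad @ 4 Gy", "3B", "4C").
* `clonality_correct()`: an identical signature seen in several cells of
  one patient x time point is scored once (kept in the lowest `cell_id`).
  Signature equality is exact string match — there is no structured
  aberration nomenclature to parse. The correction is idempotent and never
  increases a count.
* `aberration_index()` sums the four non-SCE types per cell; SCE are
  carried through parsing and frequency tables but excluded from the index
  and from ML features by default (they are not radiation-induced at low
  LET in this setting).
* `build_cell_dataset()` mirrors the telomere reshaping at cell level: 14
  patients x 2 pre-therapy samples x 30 cells = 840 rows, split 672/168 by
  the same stratified machinery. The default feature set is the single
  modelled type's count plus origin label; `joint_features = TRUE` supplies
  all four non-SCE counts (the per-cell feature definition is ambiguous in
  the emulated design, so both are available).
* The per-cell boosted models are *expected to fail* at this scale: a
  0–3-range Poisson count cannot identify a patient, so predictions
  collapse toward the grand mean and per-patient r² stays near zero. The
  acceptance suite asserts r² < 0.3 across 20 seeds — reproducing the
  negative result rather than contradicting it.

## Numerical and degenerate-input choices

* Percentile convention: interpolation type is a parameter (default 7).
* Boundary ties in length classes go to the middle class.
* Stratum train size: round half up.
* RM-ANOVA on a zero-error matrix reports F = 0, p = 1 rather than NaN.
* Degenerate inputs (empty samples, < 2 values for an SD, single patient
  in a test set, zero-variance rows or series, rank-deficient designs) are
  errors with specific messages, never silent NA propagation.
* All RNG flows through named seeds; xgboost runs single-threaded with a
  fixed seed for bit-reproducibility.

## Problem sizes used by the test and acceptance suites

The suites run the full study geometry where counts are the point (59
samples x 4600 values; 128,800-row splits; 840-cell datasets), 20-seed
replicate loops for clustering recovery and the aberration negative
control, 1000 closed-form replicates for ANOVA calibration, and miniature
cohorts (6 patients, 100 values per sample) for interface and property
tests. The complete test suite runs in about a minute on one core.

## Known limitations

* The generator's response model is multiplicative location shift only; it
  cannot express shape changes (e.g. variance inflation without mean
  change) that real irradiated distributions may show.
* In-sample r² for the OLS baselines and in-cohort (non-leave-out) boosted
  metrics are optimistic by construction; the leave-patients-out path is
  the only generalization claim.
* Clonality correction trusts signatures; without signatures it can only
  pass data through with a warning.
* Absolute telomere length (kb) calibration, image quantification, and
  dose-response biodosimetry are out of scope.
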