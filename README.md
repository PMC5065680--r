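# vitalsep

Sepsis is a leading cause of death in hospitalized patients, and the earlier
an ICU team knows it is coming, the more treatment options remain open.
`vitalsep` is an R implementation of a machine-learning pipeline that
predicts sepsis onset in ICU stays from *minimal* electronic-health-record
data — eight bedside quantities ("extended vitals": systolic blood pressure,
pulse pressure, heart rate, respiration rate, temperature, SpO2, Glasgow
Coma Score, and age) — and benchmarks it against the severity scores in
routine clinical use (SIRS, qSOFA, MEWS, SOFA, SAPS II). It is aimed at
clinical-informatics researchers who want to study vitals-only sepsis
prediction, retrospective Sepsis-3 labeling, or the robustness of EHR
classifiers to missing observations, without needing access to a restricted
clinical database: a synthetic ICU cohort generator reproduces the relevant
structure of real observation streams.

## What the package computes

**Gold standard.** Sepsis is labeled retrospectively under the Sepsis-3
definition. Suspicion of infection is the co-occurrence of a culture draw
and an antibiotic dose (culture within 72 h after the antibiotic, or
antibiotic within 24 h after the culture). Around each suspicion time a
window from 48 h before (clamped to data availability) to 24 h after
(clamped to ICU departure) is scanned over an *hourly* total SOFA score; the
first hour whose total is at least 2 points above the window-start baseline
is the onset of sepsis. Subscores without data score 0, and the respiration
subscore is a ventilation-free variant driven by the SpO2/FiO2 ratio.

**Timelines.** Raw observations are binned into one-hour bins (bin value =
mean of contained measurements), invasive arterial pressure is preferred
over cuff pressure within a bin, and gaps are imputed by carry-forward with
back-fill before the first observation.

**Features.** For a prediction hour `t`, only the two preceding hourly bins
are used: `x1` (bin `(t-1, t]`) and `x2` (bin `(t-2, t-1]`). The feature
vector is

```
xi = [ x1, x2, P(s=1 | x1^i), P(s=1 | dx^i), P(s=1 | dx^i, dx^j), P(s=1 | dx^i, dx^j, dx^k) ]
```

where `dx = x1 - x2` and the posterior-probability maps — smoothed 1-D
estimates and 2-/3-way tabular estimates over quantile-discretized deltas —
are fit on training folds only. With defaults the vector has
8 + 7 + 8 + 7 + 21 + 35 = 86 entries.

**Classifier.** Elastic-net penalized logistic regression (via `glmnet`),
class-weighted to value sensitivity and specificity equally, with the
penalty chosen by inner cross-validation. The experiment harness repeats
4-fold cross-validation over independent repartitionings and prediction
horizons of 0–4 h before onset, and a dropout harness deletes raw
observations uniformly at random (first measurement of each channel always
retained) at P in {0, .1, .2, .4, .6} before re-imputing — labels always
come from the full data.

**Evaluation.** AUROC (trapezoidal, tie-aware), area under the
precision-recall curve (average-precision step sum), and operating points
chosen so sensitivity is closest to 0.80, reporting specificity, F1,
diagnostic odds ratio, likelihood ratios and accuracy; fold-level
comparisons against a pooled benchmark use a one-sample t test.

## Worked example

```r
library(vitalsep)

cohort <- generate_cohort(synth_config(n_stays = 500, seed = 42))
#> <vs_cohort> 500 stays, 234900 observations, 208 events
#>   designed truth attached (69 septic)

timelines <- build_timelines(cohort)
labels    <- label_cohort(cohort, timelines)
head(subset(labels, is_septic), 3)
#>      stay_id is_septic suspicion_hour onset_hour baseline_sofa ...
#> 11 stay00011      TRUE             51         55             0
#> 18 stay00018      TRUE             23         29             0
#> 25 stay00025      TRUE             57         60             0

include <- apply_inclusion_criteria(cohort, labels)
include$exclusions
#>                     filter n_excluded n_remaining
#> 1             age_under_15          6         494
#> 2      no_icu_measurements          0         494
#> 3 predictor_never_recorded          5         489
#> 4     onset_outside_7_500h          0         489

cv <- run_cv_experiment(cohort, labels, include$stay_ids,
                        vs_plan(n_partitionings = 2, n_folds = 4,
                                horizons = c(0, 4), base_seed = 1),
                        timelines = timelines)
summarize_cv(cv)
#>   horizon auroc_pooled auroc_mean    auroc_sd  apr_mean
#> 1       0    0.9952899  0.9962652 0.003796273 0.9822281
#> 2       4    0.9376121  0.9420401 0.019074784 0.8264469
```

Reading the output: each septic label reports the suspicion hour, the
detected onset hour and the SOFA baseline of its detection window; the
exclusion table mirrors the sequential cohort filters (here 6 pediatric
stays and 5 stays missing a predictor channel); and the cross-validation
summary shows discrimination at onset (horizon 0) and four hours ahead —
prediction farther into the future is harder, so AUROC and APR fall with
the horizon.

A command-line wrapper covering the same stages ships in `inst/cli`:

```sh
Rscript inst/cli/vitalsep run-all --n 500 --seed 42 --out-dir run
```

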