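---
title: "Predicting sepsis onset from minimal vital-sign data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sepsis onset from minimal vital-sign data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalsep)
```

## The problem

Sepsis — life-threatening organ dysfunction caused by a dysregulated host
response to infection — is operationalized by the Sepsis-3 consensus as an
acute rise of at least 2 points in the SOFA organ-dysfunction score in a
patient with suspected infection. Detecting that event *before* it happens
would buy clinicians a treatment window, but most bedside scores either
require laboratory values or ignore trends in the data. The approach
implemented here asks how far one can get with little more than vitals:
eight quantities available at essentially every bedside (systolic pressure,
pulse pressure, heart rate, respiration rate, temperature, SpO2, GCS, age),
consumed over only the two hours preceding the prediction time.

This vignette records the model, the tunable parameters, the synthetic
cohort the package tests itself on, and the design decisions taken where
multiple reasonable choices existed.

## Retrospective gold standard

Suspicion of infection is proxied by culture/antibiotic co-occurrence: a
pair qualifies if the culture falls within 72 h after an antibiotic dose or
the antibiotic falls within 24 h after a culture draw. The suspicion time is
the first event of a qualifying pair, floored to its hourly bin. Around it,
a window of up to 48 h before (clamped to the first hour of data) and 24 h
after (clamped to ICU departure) is scanned over hourly total SOFA; onset is
the *first* hour at least 2 points above the value at the window start, and
a stay with no such hour in any window is nonseptic.

Decisions worth recording:

* **Several qualifying pairs.** Only the earliest suspicion time is used by
  the original construction; we evaluate windows in chronological order and
  accept the first that yields an onset (`try_later_suspicion_windows`,
  default on). A pre-ICU antibiotic can otherwise open a window that closes
  before the infection manifests and mask a real onset.
* **Missing subscores score 0.** A SOFA subscore whose inputs were never
  observed in the stay contributes 0 ("normal"), so vitals-only stays are
  scored from respiration, cardiovascular and CNS alone.
* **Ventilation-free respiration subscore.** The SpO2/FiO2 ratio replaces
  PaO2/FiO2 so no ventilation information is needed; the cut-points
  (400/315/235/150, config-overridable) follow the published SpO2-based
  surrogate bands, with FiO2 = 0.21 assumed when unrecorded.
* **Cardiovascular subscore without vasopressor dosing.** MAP is the
  measured channel when present, otherwise diastolic + pulse pressure / 3;
  without vasopressor channels only the MAP < 70 mm Hg tier (1 point) is
  reachable. Renal scoring uses creatinine only; a urine-output channel is
  not carried.
* **Baseline at the window start** uses the imputed hourly value (the raw
  value may not exist in that bin).

## Timeline construction

Observations are binned into half-open hourly bins `[k, k+1)` anchored at
ICU start, averaging within bins. Invasive arterial pressure is preferred
over the cuff value inside a bin (configurable); pulse pressure is the
difference of the merged systolic and diastolic channels. Imputation
carries the last observed bin forward and back-fills bins before the first
observation, so every channel that was observed at least once is complete;
never-observed channels stay flagged all-missing and downstream filters or
subscores decide their fate. Parsing rejects (and counts) events outside
per-channel plausibility ranges (HR 10–300, RR 0–80, SpO2 10–100, T 25–45
°C, systolic 20–300, GCS 3–15, ...), and accepts Fahrenheit input behind a
config flag. When no explicit ICU start exists it is approximated as 60
minutes before the first extended-vital measurement.

## Features

For prediction hour `t`: `x1` is the vector of channel values in bin
`(t-1, t]` plus age; `x2` the dynamic channels in `(t-2, t-1]`;
`dx = x1 - x2`. The feature vector concatenates z-scored `x1` and `x2`
blocks, smoothed 1-D posterior probabilities `P(s=1|x1^i)` and
`P(s=1|dx^i)`, and tabular posteriors for every pair and triple of the
seven delta channels — 86 features by default.

The posterior estimators are fit **exclusively on training folds**:

* 1-D maps use 20 equal-mass (quantile) bins — robust to the heavy tails of
  vitals — with the shrunken estimate `(n1 + a*pi)/(n + a)` per bin
  (`a = 10`, `pi` = training prevalence) and piecewise-linear evaluation
  between bin centers with constant extrapolation. Heavily tied variables
  may collapse to fewer bins; evaluation then degenerates gracefully to a
  bin lookup.
* Tables use 5 quantile bins per variable and the same shrinkage, which
  makes empty cells equal the prevalence exactly and keeps every feature
  strictly inside (0, 1).
* Standardization statistics come from the training rows only; the
  elastic-net penalty is scale-sensitive, so the `x1`/`x2` blocks are
  z-scored.

Age being static, it appears once (no `x2` or delta entry). Nonseptic
prediction hours are drawn uniformly from the eligible hours (at least
`max(2, 7 - horizon)`, mirroring the onset-at-7-h inclusion floor), seeded,
and resampled per repartitioning. Septic hours are locked to
`onset - horizon`, which the inclusion rules guarantee leaves two full bins
of history.

## Classifier and experiment design

The classifier is penalized logistic regression with an elastic-net penalty
(`glmnet`), the standard probabilistic elastic-net classifier. Classes are
weighted inversely to frequency so the model values sensitivity and
specificity equally at 11 % prevalence. The mixing parameter is searched
over {0.1, 0.5, 0.9} and the strength over a 20-step logarithmic path by
3-fold inner cross-validation on the training fold (deviance criterion);
the path is floored at `lambda.min.ratio = 0.01` because synthetic training
folds can be linearly separable, where an unbounded path chases diverging
log-odds. The experiment harness runs independent repartitionings x 4
stay-disjoint folds x horizons 0–4 h; fold assignment is stratified by
class so every fold contains both classes at realistic prevalences (a
design choice; unstratified assignment is available). Every seed — fold
assignment, nonseptic hour sampling, inner CV — derives from the plan's
base seed, making fold results bit-reproducible.

The dropout harness deletes each raw observation of the nine bedside
channels independently with probability P, always retaining the first
observation of each channel per stay, then rebuilds and re-imputes
timelines. Labels are **never** recomputed from thinned data, so the gold
standard is identical across all deletion levels, and the P = 0 arm is
bit-identical to the plain pipeline.

## Evaluation machinery

AUROC is the trapezoidal area over distinct-threshold steps, which equals
the pairwise-concordance rank statistic with ties counted one half (the
test suite asserts agreement to 1e-12 against a brute-force oracle). APR is
the average-precision step sum without PR-space interpolation. Operating
points pick the threshold whose sensitivity is closest to 0.80 (ties:
higher specificity, then lower threshold); infinite likelihood/odds ratios
are flagged rather than averaged. Fold-vs-benchmark comparisons use a
one-sample two-sided t test of fold metrics against the pooled comparator
value — the comparators are deterministic score rules, so they get a single
pooled number while the classifier gets a fold distribution; zero-variance
fold values fall back to exact comparison.

Comparator scores (SIRS, qSOFA, MEWS concurrent with the prediction hour;
SOFA and SAPS II at admission) take their published banding tables from
versioned YAML files under `inst/extdata/score_tables/`, so every cut-point
is inspectable and overridable. qSOFA's "altered mentation" is GCS < 15 —
GCS is the only mentation channel carried. SAPS II scores worst-in-window
values over the first 24 h (the original score's convention; window length
configurable) restricted to the variables the channel registry carries;
missing variables and the chronic-disease/admission items default to 0.

## The synthetic cohort

The generator emulates the structure of modern ICU EHR observation streams
so that every pipeline stage is testable without restricted data:

* **Cadence**: per-channel Poisson observation times at rates typical of
  ICU charting (HR/RR/SpO2 about 1.06–1.07 per hour, temperature 0.27, GCS
  0.25, cuff pressure 0.88; an arterial line in 43 % of stays at 0.9 per
  hour).
  Systolic/diastolic pairs share times — one cuff inflation, one transducer
  read-off.
* **Physiology**: each vital is a mean-reverting (autocorrelated) process
  around a per-stay baseline — white noise would make the two-hour delta
  features meaningless, and between-stay baseline spread (e.g. 9 bpm for
  HR) is what makes absolute thresholds imperfect discriminators.
* **Deterioration**: septic stays ramp linearly over 6–12 h into
  tachycardia (+25 /min), tachypnea (+8 /min), systolic drop (-25 mm Hg),
  desaturation (-6 %), and fever (+1.5 C), completing at the designed
  onset, with observation cadence doubled while the patient deteriorates.
  A per-stay lognormal severity multiplier (sdlog 0.5, clamped to
  [0.3, 1.6]) varies how florid the prodrome is. The GCS drop (-3) and the
  diastolic drop (-15 mm Hg) are applied as steps at onset rather than
  ramps: mentation collapse is acute, and this pins the SOFA +2 crossing
  (CNS 2 points, cardiovascular 1) to the designed hour — a partial GCS or
  MAP ramp would cross SOFA bands one to several hours early and make the
  designed onset unrecoverable by construction. A guaranteed GCS and cuff
  reassessment shortly after onset reflects practice around a
  deteriorating patient and bounds the label's detection latency.
* **Events**: septic stays get a culture 1–6 h before onset and an
  antibiotic within the qualifying window; 10 % of nonseptic stays get a
  lone decoy antibiotic (never a qualifying pair), 5 % of stays a pre-ICU
  antibiotic dose, and 2 % are pediatric — these exercise the suspicion and
  inclusion logic.
* **Demographics**: stay length lognormal with median 48 h and a long tail,
  ages normal with median about 65 (clamped 16–95), prevalence 11.3 %
  drawn binomially.

What the generator does *not* emulate: laboratory channels, real marginal
distributions beyond coarse ranges, inter-channel correlation beyond the
shared deterioration ramp, mortality dynamics, and any ambiguity in the
gold standard itself (every designed-septic stay truly crosses +2 SOFA). A
passing test suite therefore demonstrates that the pipeline recovers the
structure it defines — binning, labeling, leak-free feature fitting,
ranking — not that the classifier would attain comparable discrimination on
real ICU data, where deterioration is noisier and suspicion events are far
less cleanly tied to onsets.

## Problem sizes and numerical choices

The test suite exercises label recovery on a 500-stay cohort, signal
recovery and the qSOFA comparison on a 2000-stay cohort with 4
repartitionings at horizon 0, and the horizon/dropout trends on a
1000-stay cohort with 2 repartitionings — sizes at which fold AUROC
standard deviations are a few hundredths, small enough to resolve the
trends being asserted. The acceptance script uses 1000 stays and 2
repartitionings for every experiment. Further numerical conventions: hour
bins are half-open and 1-based internally with 0-based hour labels in all
outputs; quantile binning uses type-7 quantiles with duplicate edges
collapsed; tie-breaks at operating thresholds are deterministic (documented
above); and seeds are derived from a base seed by a fixed integer map so
that any sub-experiment can be replayed in isolation.

## Known limitations

* Vasopressor dosing, urine output and ventilation channels are not
  modeled, so the cardiovascular, renal and respiration subscores are
  conservative; real-data SOFA totals would be higher.
* The onset-time convention (integer hour bins, onset at the first
  qualifying hour) inherits the ambiguity of any retrospective Sepsis-3
  labeling; the designed-truth recovery tests quantify the pipeline's own
  consistency, not clinical ground truth.
* The comparator scores are computed from the same imputed hourly grid as
  the classifier; bedside practice computes them from spot values.
* SAPS II is restricted to the carried channels (no BUN, electrolytes,
  bicarbonate, PaO2, urine output, chronic-disease flags), which lowers its
  absolute scores; its rank ordering across stays is what the benchmark
  uses.
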