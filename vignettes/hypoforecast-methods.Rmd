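---
title: "Forecasting ICU hypotension: models, design choices, and what the synthetic cohort does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting ICU hypotension: models, design choices, and what the synthetic cohort does and does not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoforecast)
```

## The problem

Hypotension is among the most consistent manifestations of decompensation
in critically ill patients, and even brief episodes carry excess morbidity.
`hypoforecast` implements a complete minute-resolution forecasting pipeline
for the *first* hypotension event of an ICU stay: it turns raw
minute-by-minute vital signs (heart rate, respiratory rate, SpO2, systolic/
diastolic/mean arterial pressure) into a per-minute risk score in [0, 1],
and turns risk-score streams into a bedside-style alert system with a
lockout policy and alarm-burden metrics.

Because real ICU waveform databases are access-restricted, the package
ships a synthetic cohort generator with the statistical structure the
analysis assumes, so every stage of the pipeline is exercisable and
testable at desk scale. The generator is first-class, tested code, not a
fixture.

## The event definition

A minute is *below threshold* when SBP ≤ 90 mmHg **and** MAP ≤ 60 mmHg
(both inclusive; a minute with missing SBP or MAP is never below threshold
— hypotension is not inferred from absent data). A 10-minute window
sliding every minute *qualifies* when at least 5 of its minutes are below
threshold (a density criterion). The below-threshold minutes covered by at
least one qualifying window form the candidate sub-threshold periods, and
periods separated by 2 minutes or less are combined into a single
hypotension event.

Two boundary conventions deserve note. First, we read the qualifying rule
per *sliding* window, not on disjoint 10-minute blocks; the density
criterion then behaves smoothly at period edges. Second, an event's onset
is the first below-threshold minute of its merged period and its end the
last — both below threshold by construction. A consequence of keeping
only *below* minutes in the candidate periods is that a 3-minute
above-threshold gap between two sub-threshold runs splits two events even
though a bridging window may still satisfy 5-of-10, while a 2-minute gap
merges them; this matches the merge rule's intent of joining "periods
under the thresholds". The detector is verified against a brute-force
oracle that enumerates every window explicitly, on a thousand random
threshold patterns.

Subjects with at least one event form the hypotension group, keyed on the
first event only. To avoid targeting events that are really sequels of
treated, unwitnessed episodes, a hypotension-group subject is excluded when
a vasopressor, any crystalloid bolus, or a red-cell transfusion occurred in
the two hours before the first onset. We treat an intervention exactly 120
minutes (or 0 minutes) before onset as inside the exclusion window, and one
121+ minutes before as outside.

## Preprocessing

Cleaning removes physiologically implausible values using strict open
bounds — pressures outside (10, 400) mmHg, respiratory rate outside
(1, 100)/min, heart rate outside (10, 400)/min, SpO2 below 10% — so a
value exactly on a bound survives. Cleaning is idempotent.

Gaps shorter than 10 minutes are imputed causally, left to right: each
missing minute becomes the mean of the 3 most recent available values,
where values filled earlier in the same run count as available (a
signal-stability assumption). Runs of 10+ minutes are left missing, as are
leading gaps. No future value is ever used; the test suite asserts that
truncating a series after minute *t* cannot change any filled value at or
before *t*. When gaps interleave with data, "previous values" means the 3
most recent *available* observations, not the 3 previous grid minutes;
with fewer than 3 but at least 1 prior value, the mean of those available
is used. `imputation_quality()` quantifies the method by masking
known-complete segments: it is exact on constants and trails a linear ramp
of slope *s* by exactly 2*s* on single-minute masks.

## Features

Features are computed per channel on windows of 5, 10, 30 and 60 minutes
ending at the current minute (inclusive), rolling every minute:

* **statistics** — mean, sample variance (n−1), min, max, and the
  quartiles (type-7 linear interpolation between order statistics),
  computed over present values only;
* **frequency domain** — magnitudes of the 5 lowest non-constant discrete
  Fourier coefficients of the demeaned window, with residual missing
  minutes filled by the window mean so they contribute zero (this keeps
  Parseval's identity testable: with all non-DC coefficients retained,
  the spectrum energy over N equals the demeaned sum of squares);
* **EWMA** — an exponentially weighted moving average
  s_t = α·x_t + (1−α)·s_{t−1} over the window's present values,
  initialized at the first, reported at the window end. The decay α
  defaults to 0.3 and is configuration, as is the number of DFT
  coefficients: neither has a canonical value in this design, and both
  are exposed in `feature_config()`.

A window with less than half its minutes present (configurable
`min_completeness`) is skipped, and a feature row exists at a minute only
when *all* required windows pass — which is why a fully complete 120-minute
record yields rows at minutes 59..119 and a 30-minute record yields none.
The rolling kernel is compiled (Rcpp) for speed and is cross-checked
against plain-R reference implementations of every feature.

## Labels and the chronological split

Positive rows are the feature rows ending in the 15 minutes immediately
before the first onset. (A 5-minute horizon is a supported configuration
alternative; 15 is the default.) Negative rows come from two sources, both
on by default: in event stays, a 15-minute block ending 2 h 15 min before
onset — far enough that its longest (60-minute) feature window cannot
overlap any positive row's window — and in event-free stays, the 15
minutes before a *pseudo-onset* drawn uniformly within ±15 minutes of the
mean time-to-first-onset of the **training** hypotension subjects.
Pseudo-onsets are drawn per stay from an RNG stream keyed on the stay id,
so they are reproducible and independent of evaluation order. Rows between
the blocks are unlabeled: excluded from training but retained for
trajectory scoring.

The cohort is split chronologically at the median admission datetime over
all subjects — earlier-or-equal to training, later to validation, whole
subjects only — emulating prospective deployment. Ties at the median go to
training. The leakage guards (subject-level fold partitioning, the
training-only pseudo-onset anchor, positive/negative window separation,
train/validation disjointness) are asserted by recomputation in the test
suite.

## Risk models

Four classifier families are compared under subject-level tenfold
cross-validation on the training split: a random forest (500 trees), KNN
(k = 11, standardized features), gradient boosted trees (100 rounds,
depth 3, learning rate 0.1), and L2-regularized logistic regression
(ridge, λ = 1). None of these hyperparameters is canonical for this task;
all are exposed in `model_spec()` and fixed defaults are reported with the
fit. Folds partition subjects, stratified on group membership, so no
subject's minutes straddle a fold. Class imbalance is handled by reporting
AUPRC rather than by resampling.

Selection follows a calibration-first rule: among families whose mean CV
AUROC is within 0.02 of the best, the lowest Brier score wins. The chosen
family is then re-cross-validated keeping the per-fold models, so that the
training stays can be scored *out of fold* — the stacked second stage (see
below) is trained on first-stage scores that are honest for every training
subject.

## Trajectories and evaluation

Scoring the validation stays every minute yields per-stay risk
trajectories, aligned at the first-event onset (hypotension stays) or the
pseudo-onset (event-free stays) so both groups share a lead-time axis.
Group means carry normal-approximation 95% confidence intervals
(mean ± 1.96 se) — a bootstrap would also be defensible, but
plot-matching precision is not the goal and the normal approximation keeps
the summary analytic.

Discrimination is evaluated *per lead time*: at lead L the positives are
hypotension-stay scores exactly L minutes before onset and the negatives
are event-free-stay scores L minutes before pseudo-onset (instantaneous
slices, not cumulative windows; when the exact minute is unscored the
nearest within ±1 minute is accepted). AUROC uses the Mann–Whitney
mid-rank formulation (ties count half); AUPRC uses step-wise average
precision with ties entering in groups, which makes both exactly equal to
their brute-force oracles (pairwise concordance; threshold enumeration) on
small instances. Calibration is the Brier score with 10 equal-width
reliability bins. Patient-level AUPRC aggregates each stay to its maximum
score over either the whole scored span or a seeded random hour.

## The alert system

Raw alert candidates are minutes whose score meets or exceeds the
threshold (inclusive; default 0.5). The stacked second stage re-scores each
minute from summaries of the first-stage score stream — time since
admission plus mean/min/max/sd over trailing 5-, 10- and 30-minute
lookbacks (sd of a single score is 0) — and is trained with the same
subject-level CV contract on the same labeled minutes. A 15-minute lockout
is applied greedily: a candidate is emitted only when more than 15 minutes
have passed since the previously *emitted* alert (not the previous
candidate). Alerts are adjudicated per stay: true positive iff the stay's
first event starts strictly after the alert (any pre-onset alert counts by
default; a finite horizon is a config option), false positive otherwise —
including every alert in an event-free stay. Post-onset minutes are not
alerted on in this first-event analysis. The alert burden divides by
monitored (scored) subject-hours, not nominal record length; both
denominators are recoverable from the outputs.

## The synthetic cohort

The generator emulates what the analysis needs and nothing more:

* a 1-minute grid with subject-specific baselines (HR 80 bpm, RR 16/min,
  SpO2 97%, SBP 120 mmHg, DBP 70 mmHg by default) and AR(1) noise per
  channel (coefficient 0.9) — minute-scale vitals are strongly
  autocorrelated, and AR(1) is the simplest process with that property;
* MAP derived as (SBP + 2·DBP)/3 plus unit noise, keeping the pressure
  channels physiologically coupled rather than independent;
* a programmed decompensation for hypotensive subjects: SBP and DBP glide
  linearly from 90 minutes before the programmed onset to just above the
  event thresholds, then drop at the onset to a plateau 35 mmHg (SBP;
  70% of that for DBP) below baseline, hold for 30 minutes and recover
  over 60; heart rate rises ~10 bpm in parallel, giving a multi-channel
  pre-event signature;
* missing-data bursts (up to 5 consecutive minutes, 5% of minutes by
  default), and out-of-range artifacts that are guaranteed to violate a
  plausibility bound so cleaning provably removes exactly the injected
  positions;
* admission datetimes uniform over 30 days, so the chronological split is
  well defined.

Two construction guarantees are worth stating plainly, because they are
generator *design*, not incidental behaviour. The first 15 post-onset
minutes are capped below the definitional thresholds, so every programmed
event satisfies the event definition on the clean series. Conversely,
outside the programmed event window — including during the pre-onset
glide — any minute that a noise excursion would push below *both*
thresholds is nudged back above them. The glide therefore approaches but
never crosses the joint threshold, and the detected onset coincides with
the programmed onset exactly; this two-segment shape (glide, then terminal
drop) was chosen over a single linear ramp to −35 mmHg precisely because a
single ramp crosses the thresholds minutes before the programmed onset and
makes "the" onset ill-defined.

What the synthetic cohort does **not** emulate: circadian and treatment
dynamics, waveform-granularity structure, patient heterogeneity in event
depth and speed, repeated episodes, and artifacts *within* physiologic
range. Passing the recovery tests therefore shows that the pipeline's
machinery is correct and leak-free and that it recovers a programmed
signal of realistic shape — it does not certify clinical performance on
real ICU data, where the corresponding headline numbers are
database-dependent.

One consequence of the short synthetic records is visible in the
patient-level analysis: with 8-hour scored spans, aggregating over a
random hour usually *misses* the 90-minute pre-onset surge of the
positives, so whole-stay AUPRC exceeds random-hour AUPRC here, whereas on
multi-day real records the whole-stay mode is the one burdened by
accumulated false peaks in the negatives. Both modes are computed and
reported.

## Problem sizes and numerical choices

The recovery analysis runs at 200 subjects, 50% hypotensive, 24-hour
records — large enough for ~50 validation subjects per group and stable
lead-time curves, small enough for a desk-scale run. Validation (and
training, for the stacked stage) stays are scored over the 480 minutes
preceding each stay's onset or pseudo-onset; this covers the 4-hour
trajectory window with margin and is the monitored span used in the
alerts-per-subject-hour denominator. Cross-validation uses k = 10 at this
scale (structural tests use smaller k with smaller cohorts). All
randomness — cohort, pseudo-onsets, fold assignment, model fits,
random-hour draws — flows from explicit integer seeds, and rerunning the
pipeline with the same configuration reproduces every CSV output byte for
byte; single-threaded fits are used throughout so determinism does not
depend on scheduling.

Degenerate inputs are handled explicitly: stays shorter than 10 minutes
yield no events; series shorter than the largest feature window yield no
feature rows; a stay shorter than its pseudo-onset is skipped with a
warning; all-identical admission dates make the chronological split an
error rather than a silent empty validation set; windows with a single
present value report variance NA (and such rows are dropped) while the
stacked stage's single-score sd is 0 by convention; an empty alert stream
yields zero burden and undefined PPV.

## Known limitations

* The generator's parameters are stand-ins chosen for testability; no
  distributional fidelity to any real ICU population is claimed.
* Only the first event per stay is modelled; subsequent-episode dynamics
  (and their dependence on interventions) are out of scope.
* Cross-channel correlation features are deliberately absent.
* The per-stay risk trajectories summarize a group mean; individual
  trajectories vary widely, and the group band is not a statement about
  any single patient.
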