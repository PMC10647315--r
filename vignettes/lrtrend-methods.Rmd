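---
title: "Longitudinal radiomic trend analysis: models and design choices"
author: "lrtrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal radiomic trend analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtrend)
```

## The problem

Patients with locally advanced rectal cancer receive a fractionated course
of radiotherapy (typically 28 daily fractions), and a cone-beam CT (CBCT) is
acquired before every fraction for positioning. Those daily scans are an
untapped window on how the tumour is responding *during* treatment: if
responders and non-responders could be told apart by mid-course, treatment
could be adapted — for instance sparing a complete responder an invasive
resection. The difficulty is that single-time-point radiomic features from
CBCT are noisy and poorly reproducible, and cohorts are small, so
conventional high-dimensional radiomic models overfit badly.

`lrtrend` implements a longitudinal trend analysis that sidesteps both
problems: instead of modelling 1688 features at one time point, it models
the *temporal trend* of each feature across the daily scans and reduces
every (patient, feature) series to a single trend statistic. The package
covers the full pipeline — registration quality control, per-patient
normalization, least-squares trend fitting, two-stage feature screening,
a random-forest classifier plus an interpretable statistical-weight (SW)
classifier, and a per-fraction-cutoff leave-one-out evaluation with a
consistency audit — together with a synthetic-cohort simulator so that
every stage is testable without patient data.

## The trend model

For a patient, let $X_j$ be the number of delivered fractions
($X_j = 1, 2, \dots, N$) and $RF_{ij}$ the (normalized) value of feature
$i$ at fraction $j$. The model is an ordinary least-squares line per
feature,

$$RF_{ij} = \mathrm{LRT}_i \cdot X_j + \beta_i,$$

where the slope $\mathrm{LRT}_i$ is the longitudinal radiomic trend and
$\beta_i$ the intercept. The fit error $\mathrm{ERR}_i$ is the mean
*absolute* residual: the signed residuals of an OLS fit sum to zero
identically, so only an absolute (or squared; available via
`errorType = "rmse"`) residual summary carries information. The trend
statistic used for everything downstream is

$$\mathrm{LRTF}_i = \mathrm{LRT}_i + \beta_i,$$

numerically the fitted value at the first fraction. Adding a slope
(per-fraction units) to an intercept is only meaningful because both are
computed on dimensionless z-scores; we implement the sum literally.

### Normalization

Trend analysis cares about the *shape* of each patient's series, not its
magnitude, so each (patient, feature) series is standardized with its own
mean and sample (n−1) standard deviation, and the resulting z-scores are
clipped to $[-3, 3]$. Clipping rather than discarding keeps the fraction
grid intact for the trend fit; a discarded scan would perturb the design
matrix for all 1688 features of that patient. Constant series (zero
variance) map to all zeros and are flagged; trend fitting omits them for
that patient, and they enter downstream feature matrices at 0, which is
exactly their normalized value. Whether clipped values should instead be
excluded from fitting is not settled by the method's description; bounding
is this package's documented choice.

A consequence worth knowing: z-scoring destroys slope *magnitude*
information within a series (any clean monotone line of whatever slope
normalizes to the same sequence). Group signal therefore lives in the
trend's direction and shape consistency across features, which is what the
screening and orientation machinery below exploits.

## Feature schema

The canonical feature vector mirrors a standard radiomics extraction from
a contoured target volume (GTV or PTV): 14 shape features from the
original image, plus 93 features (18 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 14 GLDM, 5 NGTDM) from each of 18 image types — the original
image, Laplacian-of-Gaussian filtered images at $\sigma$ = 0.6, 1.0, 3.0
and 5.0 mm, the 8 wavelet high/low band combinations, and gradient,
square-root, logarithm, exponential and square transforms:

$$18 \times 93 + 14 = 1688.$$

Voxel-level feature extraction is deliberately out of scope: any backend
that writes the long CSV contract (`patient_id,fraction,feature_id,value`)
can feed the pipeline, and `buildDefaultSchema()` fixes stable feature
identifiers. Which wavelet band maps to which identifier is treated as an
opaque naming choice. The registration that precedes extraction is likewise
pluggable; the package audits its six rigid-transform parameters per
fraction against the manually verified day-1 registration, warning when
any parameter deviates by more than 5%. Relative deviation is undefined
for near-zero day-1 parameters, so the denominator is floored at 1 mm /
1 degree — the floor rule is this module's decision, as is the
parameter-wise (rather than matrix-norm) comparison, chosen because it is
auditable per axis.

## Screening and classifiers

At a treatment-length cutoff $N$, each patient is reduced to a vector of
LRTF values over features, and:

1. **Mann–Whitney screen.** Each feature's LRTF is compared between
   responders and non-responders with a two-sided U test (exact when the
   sample is untied, tie- and continuity-corrected normal approximation
   otherwise); features with $p < 0.05$ are retained. Raw p-values are
   used by design — they parameterize the SW model below — with
   Benjamini–Hochberg available as an option.
2. **Univariate logistic screen.** Each survivor is fitted as the single
   covariate of a logistic regression in leave-one-out cross-validation
   and kept when its held-out accuracy reaches a threshold (default 0.7;
   1.0 demands every fold correct). The criterion "correctly classified in
   the validation set" is not fully specified in the method's description;
   a configurable accuracy threshold brackets the plausible readings.
   Perfect separation is handled by clamping the coefficients, so
   predictions saturate instead of diverging. If nothing survives, models
   fall back to the U-retained set with a warning.
3. **Random forest.** A seeded probability forest (500 trees, grown to
   pure leaves) on the retained LRTFs; the RF score of a patient is the
   predicted responder probability.
4. **Statistical-weight (SW) model.** Each retained feature gets weight
   $w_i = (0.05 - p_i)/0.05$ — 0 at the significance boundary, 1 for a
   vanishing p-value — and an orientation sign $s_i = \pm 1$ by whether
   responders' mean LRTF exceeds non-responders' in the training data. A
   patient's score is $\sum_i w_i s_i \mathrm{LRTF}_i / \sum_i w_i$, and a
   score above 0 suggests a responder. The weight normalization makes the
   0 threshold meaningful regardless of how many features were retained,
   and duplicating a feature cannot change the score. Orientation is an
   extension (default on, `orient = FALSE` for a literal unsigned
   average): without it, informative features trending in opposite
   directions cancel. Weighting LRTF directly or weighting LRT and
   $\beta$ separately with a common weight coincide by linearity; that is
   the implemented reading.

## Evaluation design

A 28-fraction course defines 27 experiments, one per cutoff
$N = 2, \dots, 28$. For each experiment the table is restricted to
fractions $1..N$, normalized, trend-fitted, and evaluated by leave-one-out
cross-validation over patients: screening, the logistic filter, the
forest and the SW weights are all rebuilt inside each training fold, so
the held-out patient's label can never influence its own score (a property
tested directly, and indirectly via a label-permutation null). Per-patient
z-normalization depends only on that patient's own series and is
leakage-free by construction; it is computed on fractions $1..N$, the data
a prospective user would have at that point.

Per experiment the suite records held-out RF and SW scores, accuracy, and
the pooled AUC over held-out scores; the headline AUC is the mean over
experiments. Accuracies are additionally summarized over three
treatment-length bands — N 2–14, 15–20 and 21–28, partitioning the 27
experiments as 13 + 6 + 8 — which is where the method's clinically
relevant pattern shows: accuracy climbs early in the course and
stabilizes after roughly fraction 15.

The **consistency index** of a patient is the fraction of experiments in
which the patient was correctly classified. Patients whose mean
consistency over the late-course window ($N \ge 15$) exceeds 0.8 form the
high-consistency group; low-consistency patients are the ones for whom
high headline metrics should be treated with caution. The index is
computed per patient over all experiments (a per-patient definition is
the only reading of the method's description that types correctly).

### Small-cohort limits of the screen

With an exact two-sided U test, the smallest achievable p-value for group
sizes $(n_1, n_2)$ is $2/\binom{n_1+n_2}{n_1}$. Inside a leave-one-out
fold of a cohort with 4 responders and 4 non-responders, that minimum is
$2/35 \approx 0.057 > 0.05$: *no* feature can be retained, and the suite
degrades to neutral fallback scores. This is a genuine property of the
method, not an implementation artifact; the package emits flagged neutral
scores (RF 0.5, SW 0) rather than failing. Cohorts of ten or more
patients with both classes represented are needed for the default screen
to have any power, and the 30-patient default is comfortably above that.

## The synthetic cohort

The simulator generates, for every (patient, fraction, feature),

$$\text{value} = \text{intercept} + \text{slope} \cdot X_j + \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),$$

which is precisely the generative family the trend model assumes. A chosen
subset of features is *informative*: in responders their slopes centre on
`effect_slope_mean`, in non-responders (and for every non-informative
feature, as background drift) on zero, all with spread `effect_slope_sd` —
so the group *difference* in trend, not the absolute slope, carries the
signal. Labels are assigned deterministically (the first
$\lceil n \cdot \text{fraction\_responders} \rceil$ patients respond) so
label counts do not jitter across seeds. Scans can be dropped at a
`missing_rate` (never below two per patient), and values replaced by gross
outliers at the true line value $\pm 10\sigma$, which exercises the
$|z| = 3$ bounding.

Defaults are the study conditions the package targets: 30 patients, 28
fractions, 1688 features, 14/30 responders, 40 informative features,
`effect_slope_mean` 0.05 (so the informative trend sweeps about 1.4 units
over the course), `effect_slope_sd` 0.02, `noise_sd` 0.2, no missing scans
or outliers. These were chosen once as a realistic mid-strength scenario —
per-fraction noise several times the per-fraction trend, signal clearly
emerging over tens of fractions — and give the qualitative behaviour the
method reports on real data: near-perfect late-course RF separation,
noticeably weaker and flatter SW accuracy, and consistency rising after
fraction 15.

What the simulator does **not** emulate: CBCT artifacts and image-quality
drift, inter-feature correlation (real radiomic features are strongly
collinear), non-linear response trajectories, and class-dependent feature
variance. Passing tests on simulated cohorts therefore demonstrate that
the pipeline recovers the signal class it assumes — linear group-dependent
trends in independent Gaussian noise — not that the clinical performance
figures transfer to any particular scanner or cohort.

## Numerical choices

* OLS is solved in closed form from centred sums; fits match a
  normal-equations solve to $10^{-10}$ and are exercised against that
  oracle in the tests.
* Mann–Whitney p-values are exact (via the `pwilcox` distribution) when a
  column is untied; ties switch to the tie-corrected normal approximation
  with continuity correction, mirroring `stats::wilcox.test`, which —
  together with exhaustive permutation enumeration — serves as the test
  oracle. The screen is compiled because the evaluation calls it for
  every (experiment, fold) pair.
* The univariate logistic LOOCV screen is a compiled Newton iteration
  with a closed-form 2×2 solve and coefficients clamped to ±30;
  `stats::glm` is its test oracle. Clamping doubles as the
  perfect-separation fallback.
* The random forest is `ranger` with a fixed seed and one thread for
  exact reproducibility; `min.node.size = 1` grows probability trees to
  pure leaves (the backend's probability-forest default of 10 cannot even
  split a 9-patient training fold). Seed 0 is mapped to a nonzero backend
  seed because the backend treats 0 as "unseeded".
* AUC is `pROC` on pooled held-out scores; tests recompute it from the
  rank-statistic identity $U/(n_1 n_2)$. Constant score vectors are
  reported as AUC 0.5.
* Ties at the decision thresholds (RF score exactly 0.5, SW score exactly
  0) classify as non-responder — the conservative direction for a score
  whose positive side means "responder".

## Problem sizes used in the shipped checks

The package's own test battery runs cohorts of 4–30 patients with 10–200
features; the end-to-end recovery and permutation-null checks use 20
seeds each at 30 × 28 × 200 (with 40 informative features, effect 0.15,
noise 0.1 — effect far above noise, per-fraction) and 16 × 28 × 80
respectively. The acceptance script runs the full default cohort
(30 × 28 × 1688) once. These sizes were chosen so the whole battery
completes in minutes on a laptop while still exercising the full
27-experiment design at the canonical feature count.

## Known limitations

* The SW model's 0 threshold presumes oriented scores centred between
  groups; when non-responders' informative trends are sign-symmetric
  (as under the simulator's null drift), their scores straddle 0 and SW
  accuracy saturates well below the forest's — matching the method's own
  reported gap between the two models.
* The logistic screen's "validation set" reading, the clipping-vs-exclusion
  choice, and the per-patient consistency definition are places where the
  method's description is ambiguous; each implemented reading is flagged
  above and configurable where feasible.
* Fit errors are reported in z-units; they are comparable across features
  and patients but not across differently-normalized analyses.
* No multiple-testing correction is applied by default (the SW weights
  require raw p-values); interpret retained-feature counts accordingly.
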