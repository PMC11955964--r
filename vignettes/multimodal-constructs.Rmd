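---
title: "Multimodal biometric constructs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal biometric constructs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomconstruct)
```

## The problem this package addresses

Tablet gaming sessions in children yield three synchronous behavioural
streams: gaze directions from the front camera (about 28 frames/s), touch
events from the screen (about 100 Hz), and per-frame emotion class
probabilities produced by an upstream facial-expression classifier. The
question is whether low-dimensional summaries of these streams — "biometric
constructs" — carry information about neuropsychological measures relevant
to ADHD symptomatology (WISC-V subtests, ADHD rating scales, CBCL social
problems, grit/achievement, handedness), and whether combining modalities
beats any single one.

`biomconstruct` implements that analysis end to end:

1. per-challenge feature extraction (4 eye-tracking, 5 digit-tracking and
   7 emotion features — 16 in all);
2. 100-bin time-normalisation of each feature series per challenge;
3. PCA on the binned matrix, fitted on a *reference* cohort and transferred
   by its eigenvectors to the analysis cohort, retaining three components
   (MBC1–MBC3);
4. linear mixed models of age/sex-adjusted measures on the constructs, with
   the game's challenges as a random intercept (REML), plus a robust
   (Huber) counterpart;
5. Holm–Bonferroni correction across the screening family and Cohen's D
   effect sizes;
6. a multimodal-vs-unimodal comparison by mean absolute error (MAE).

Because no public cohort exists for this design, the package ships a
synthetic generator with known ground truth; every stage is tested against
it and against independent oracles.

## Feature definitions

**Eye tracking.** For consecutive unit gaze vectors $a, b$ the angular
distance is $\alpha = \cos^{-1}\!\big(a\cdot b / (|a||b|)\big)$ in degrees;
angular velocity is $\alpha/\Delta t$; total angular distance is the running
sum $\sum|\alpha|$. Fixations and saccades come from velocity-threshold
identification (I-VT): intervals with velocity strictly below the threshold
(default 100°/s) are fixations, intervals at or above it are saccades;
consecutive same-label intervals merge into events, and fixation events
shorter than the minimum fixation duration (default 70 ms) are relabelled
*undefined*. Two readings were genuinely open:

* **Ties at the threshold** classify as saccade, because fixations are
  defined by velocities strictly *below* the threshold.
* **Sub-minimum fixations** become undefined rather than being merged into
  neighbouring saccades: a duration criterion is stated for fixations, but
  no merge rule, so exclusion is the conservative choice. Undefined
  intervals enter the binned saccade-indicator series as missing values.

No velocity smoothing is applied before thresholding; a causal
moving-average option exists downstream (`smooth_series()`, window 1 = off
by default).

**Digit tracking.** Per gesture: mean point-to-point speed (zero-$\Delta t$
duplicates collapsed first, so division by zero is impossible), area of the
minimal convex polygon over the gesture's points (the convex hull, computed
by `chull` + shoelace — "minimal adaptive polygon" is not a defined term,
and the hull is the canonical deterministic minimal convex cover), summed
point-to-point distance, duration, and vertical extent
$\max(y) - \min(y)$ (invariant to the screen-origin convention). A
single-point gesture scores zero on every feature. Gesture series are
indexed by gesture midpoint time.

**Emotion.** Seven probabilities (anger, disgust, fear, happiness, neutral,
sadness, surprise) per frame are *inputs*; the classifier that produces
them is out of scope. Values must lie in $[0,1]$; optional simplex
normalisation is off by default since upstream outputs are only guaranteed
to be bounded, not normalised.

## Binning and the construct model

Each feature series is averaged into 100 equal-width time bins over
$[0, \mathrm{duration}]$ (half-open bins, last bin closed). Empty interior
bins are filled by linear interpolation between the nearest non-empty bins;
empty leading/trailing bins carry the nearest value; an entirely empty
series (e.g. a challenge without touches) stays missing. These fill rules
are the simplest deterministic completion; they are applied before any
statistics, so they cannot leak information across rows.

Rows of the binned matrix are (participant, challenge) pairs — not
per-participant concatenations — so that challenge can act as the mixed
model's random effect; columns are feature × bin in fixed feature-major
order (16 × 100 = 1600 multimodal columns). Unimodal matrices are exact
column slices (`subset_modality()`).

`fit_reference()` imputes missing cells by column mean, standardises
columns (zero-variance columns dropped and recorded), and takes the top
three right singular vectors, with the sign convention that each
component's largest-magnitude loading is positive — this makes the PCA
deterministic across linear-algebra backends. Standardisation before the
eigendecomposition is on by default: the 16 features live on wildly
different scales (degrees, pixels², probabilities), and an unstandardised
PCA would be dominated by the pixel-scale features.

`project_constructs()` applies the *reference* means, sds and eigenvectors
to the analysis cohort. Nothing of the target cohort enters the
standardisation or rotation — tested by asserting identical scores under
row permutation and subsetting of the target matrix.

## Association models

For each measure, raw scores are z-adjusted against an age-band × sex
normative table (bands [7,9), [9,11), [11,13), [13,15]), then modelled as

$$ z_{ic} = \beta_0 + \beta_1\,\mathrm{MBC1}_{ic} + \beta_2\,\mathrm{MBC2}_{ic}
   + \beta_3\,\mathrm{MBC3}_{ic} + u_c + \varepsilon_{ic}, \qquad
   u_c \sim N(0, \sigma_u^2), $$

fitted by REML (`lme4::lmer`). Wald (normal-approximation) p-values are
reported per fixed effect; residual normality (Shapiro–Wilk) and
homoscedasticity (Spearman correlation of |residual| with fitted) are
attached as diagnostics. Singular fits — likely with only 6–11 challenge
levels — are flagged and reported with zero random variance, never
discarded. The robust flavour uses Huber M-estimation with challenges as
fixed indicators, because robust mixed models are not standard; it is an
approximation documented as such.

The Holm–Bonferroni family is **all (measure × component) tests within one
game and model flavour** — the widest defensible family, since the original
family definition is not recoverable; it is what `run_associations()`
corrects over by default. Cohen's D per significant component is the
standardised difference of the target between rows above and below that
component's median score.

## The MAE comparison

For every measure, one model per modality set (multimodal, eye, touch,
emotion) is fitted and its in-sample MAE computed from fixed effects plus
estimated challenge effects. Each unimodal model is reported as the percent
change relative to the multimodal baseline (indexed 1):
$100\,(\mathrm{MAE}_{u} - \mathrm{MAE}_{m})/\mathrm{MAE}_{m}$, rounded to
integers in the report layout but stored unrounded. In-sample evaluation
matches the comparison's purpose (relative model adequacy, not out-of-sample
validation); a cross-validated variant would be a natural extension but is
deliberately out of scope.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical structure* the analysis relies
on, with defaults fixed at the study's conditions: 24 analysis children and
63 reference children; 11 Rocket and 6 Connect challenges per child; gaze
at 28 Hz and touch at 100 Hz. Values the design leaves open were chosen
once on field-typical grounds and not revisited:

* **Challenge durations** 20 s (Rocket) and 30 s (Connect): short gamified
  sub-tasks in the 15–30 s range.
* **Fixation dwell** mean 0.35 s (typical free-viewing fixations are
  200–400 ms), minimum 150 ms so fixations always survive the 70 ms filter.
* **Saccades** follow a raised-cosine velocity profile (smooth, peaked,
  guaranteeing unambiguous threshold crossings), mean amplitude 12° with a
  floor of 9.5° — at 28 Hz sampling the floor ensures at least one
  inter-sample interval exceeds 100°/s even when a saccade straddles a
  sample boundary — and mean peak velocity 400°/s (main-sequence scale for
  10° saccades).
* **Fixation jitter** 0.25° per sample (≈ 7°/s, far below threshold);
  set it to 0 for noise-free traces whose saccade count the I-VT stage
  recovers exactly.
* **Touch** gestures are smoothed random polylines at mean 600 px/s,
  roughly 0.4 gestures/s.
* **Emotion** frames are temporally smoothed Dirichlet draws on the
  7-simplex, neutral-dominant at baseline.

Three standard-normal latent factors per participant (oculomotor, motor,
arousal) scale, respectively, saccade rate/amplitude, gesture speed, and
the Dirichlet concentration; per-challenge random multipliers (log-sd 0.2)
play the role of the challenge random effect. Raw assessment scores are the
age/sex normative mean plus the loading-weighted latents (on the
normative-sd scale) plus Gaussian noise (sd 0.6), so scores are generated
on the raw scale and the z-adjustment is exercised end to end. The
synthetic normative table has strictly increasing means in age and positive
sds everywhere.

What passing tests on this generator **do** show: the feature formulas,
event detection, binning, reference-transfer PCA, mixed-model inference,
multiplicity correction and MAE accounting are implemented correctly, and
the pipeline recovers programmed signal at realistic sizes. What they **do
not** show: that real children's gaze, touch or affect look like these
distributions, nor that the constructs' clinical associations replicate —
the generator makes no claim of behavioural realism and no
ADHD-subtype-specific structure.

## Numerical choices and degenerate inputs

* Gaze vectors within $10^{-3}$ of unit length are renormalised; anything
  further off is rejected with the offending row. All other invariant
  violations (non-monotone timestamps, out-of-range probabilities, missing
  stream files) are hard, located errors — never silent coercion.
* Angular cosines are clamped to $[-1, 1]$ before `acos`.
* Zero-variance columns are dropped at PCA fit time and recorded in the
  model so projection can verify column compatibility.
* Empty touch challenges propagate as missing bins, mean-imputed at PCA
  time and reference-mean-imputed at projection time.
* All writers serialise numerics at 17 significant digits; writer/reader
  pairs round-trip at $10^{-12}$ relative tolerance.

## Problem sizes used by the test suite

The suite validates oracle equivalences at full scale (1000 random I-VT
traces, 500 random hulls, 1000 random p-vectors), inference calibration at
n = 60 rows (100 coverage simulations, 500 null fits), and the modality
comparison on 50 simulated cohorts per scenario of 10 + 12 children with
shortened challenges (4–8 s) — sizes chosen to exercise every code path at
comfortable desk scale. The acceptance script runs the full pipeline at the
study's own scale (24 + 63 children, full-length challenges).

## Known limitations

* The moving-average treatment is causal smoothing, not a fitted MA(q)
  error model; the motivating description is compatible with both and the
  estimation procedure for the latter is unspecified.
* Whether the binned saccade feature should enter as the per-interval
  indicator series or as event summaries is ambiguous; both are computed,
  and binning consumes the indicator series by default.
* The robust flavour's fixed challenge indicators are not exactly
  exchangeable with the mixed model's random intercept.
* In-sample MAE favours larger modality sets slightly; comparisons should
  be read as relative adequacy, not generalisation error.
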