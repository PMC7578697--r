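---
title: "Methods: simulating and classifying prefrontal fNIRS responses to auditory attention tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying prefrontal fNIRS responses to auditory attention tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscit)
```

## The problem

Minimal hepatic encephalopathy, the earliest neurocognitive stage of
chronic liver disease (CL), is routinely screened with paper-and-pencil
batteries (number connection tests, digit span). A complementary
physiological marker is the prefrontal haemodynamic response during
auditory attention: patients and healthy controls (HC) differ in how
oxygenated haemoglobin (HbO2) rises over the frontal cortex while they
identify melodic pitch contours under increasing distraction. `nirscit`
implements the full analysis chain for such a study — symbolic task
design, fNIRS preprocessing, linear-SVM classification with exhaustive
channel-subset selection — together with a seeded synthetic-data
generator, so that every stage is testable end to end without access to
any recording.

## Task design

A contour identification task (CIT) item is an ordered pair of distinct
pitch-contour directions (ascending, stationary, descending), giving
$3 \times 2 = 6$ pairs; modulated in five major keys (the chromatic span
G#, A, A#, B, C — the span is named by its endpoints, the intermediate
keys are our reading) and played in three timbres (piano, flute,
string), for $6 \times 5 \times 3 = 90$ items. Each item lasts
$2 \times 2250 + 750 = 5250$ ms. A session presents three 18-item
blocks: CIT1 against environmental-sound distractors, CIT2 against
target-like contours in another timbre, CIT3 with an attention-shift
cue per trial. Stimuli are symbolic (direction/key/timbre labels plus
timing); no audio is rendered. The response window and the CIT3 cue
schedule are not fixed by the study description; we default to
measuring reaction time from item offset and to randomising which
contour line is cued first under the block seed.

## Preprocessing

Raw two-wavelength intensities are converted to HbO2/HHb concentration
changes by the modified Beer–Lambert law,
$\Delta OD_\lambda = -\log_{10}(I_\lambda / I^0_\lambda)$ and
$\Delta c = (E\,d\,\mathrm{DPF})^{-1} \Delta OD$. The instrument
constants are not part of the study description; we default to
770/840 nm, DPF 6.0 at both wavelengths, a 3 cm source–detector
separation and standard adult extinction coefficients (in
mM^-1^cm^-1^), all configurable. Concentration units are then mM.

The series is band-passed at 0.01–0.09 Hz with a 3rd-order Butterworth
filter applied forward–backward (zero phase), with reflection padding of
about one period of the low cut-off at the edges. Each channel is then
standardised by subtracting its mean over the 20-s pre-stimulus
baseline ("standardised" is read as mean subtraction; a z-scoring mode
is available). Finally each task block is reduced to its per-channel
mean HbO2 over `[block start + 10 s, block end)`; the excluded onset
window accounts for the delayed haemodynamic rise. The description "the
first 3–10 s" is ambiguous between a fixed 10-s exclusion and a
per-analysis choice; we default to 10 s and expose the parameter.

A 30 + 25 subject cohort with three CITs yields
$55 \times 3 = 165$ feature rows; the classification table keeps CIT1
and CIT2 only (110 rows), because the third task is behaviourally
saturated for the patient group and its haemodynamics do not index a
comparable load. Class encoding is CL = +1, HC = −1.

## Classifier and evaluation

The classifier is a linear soft-margin SVM,
$\min_w \tfrac12\lVert w\rVert^2 + C\sum_i \max(0, 1 - y_i(w\cdot x_i + b))$,
with $C = 1$ fixed across all subsets for comparability (the study does
not report $C$). The dual is solved by sequential minimal optimisation
with maximal-violating-pair selection, second-order working-set choice,
shrinking of bound points, and warm starts inside cross-validation; a
solver written in C++ is used because the exhaustive search performs
millions of fits. Its solutions are cross-checked in the test suite
against both an independent libsvm implementation and a brute-force
active-set enumeration of the KKT system on small instances. A decision
value of exactly zero is classified positive (only the strict
inequalities are defined by the model).

Performance is evaluated by stratified 5-fold cross-validation repeated
20 times. Fold assignment is a pure function of the master seed and the
repeat index, so every channel subset is compared on identical
partitions. From each test fold's confusion matrix we compute
sensitivity, specificity, accuracy, the Matthews correlation
coefficient
$\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$
(defined as 0 when any denominator factor vanishes) and balanced
accuracy $(\text{sens}+\text{spec})/2$; MCC and bACC are robust to the
30/25 class imbalance. Note that sample-level folding lets the two CIT
rows of one subject fall into train and test of the same split; this
follows the original design, and a subject-grouped mode is provided
(`make_subject_folds`, passed through the `folds` argument).

## Exhaustive subset search

For a grouping (right CH1–CH8, left CH9–CH16, bilateral CH1–CH16) every
non-empty channel subset — $2^8-1 = 255$ per hemisphere, $2^{16}-1 =
65{,}535$ bilaterally — is cross-validated and ranked by mean MCC, with
ties broken by mean bACC, then smaller size, then lexicographic order.
The full bilateral search takes a few minutes on one core at the
looser cross-validation tolerance; a `max_size = 6` cap (14,892
subsets) runs in about half a minute and is used throughout the
analysis scripts. Subsets are evaluated in prefix
order so each inherits warm-start dual solutions from its parent; the
ranking is independent of evaluation order. The weight-sign matrix
refits the SVM on the full table for each of the top 50 subsets and
records each member channel's signed weight (positive = higher HbO2 in
CL); fold-averaged weights would be an alternative, but one refit per
subset is the simplest reading of a single weight per subset–channel
cell.

## The synthetic-data generator

Each subject's session is synthesised on a fine grid (dt = 0.05 s,
decimated to the instrument's 0.65 s) as a boxcar over the three task
blocks convolved with a delayed double-gamma response kernel (peak 6 s,
undershoot 16 s, ratio 1/6, onset delay 5 s; normalised to unit
integral so a long block plateaus at its amplitude), plus noise:
cardiac pulsation (~1.1 Hz — above the 0.77 Hz Nyquist rate, so it
aliases into the decimated series exactly as in a real recording, and
the band-pass must remove it), ~0.1 Hz vasomotion, linear and
random-walk drifts, white measurement noise, and multiplicative
response-gain variability at the subject, channel and block level.
HHb is a negatively scaled copy of the response. The session layout is
20 s baseline, three 94.5-s blocks (18 items x 5.25 s), 20-s rests and
a 20-s post-task period.

Group effects are planted as amplitude offsets for the CL group at
CH6/CH7/CH10 (positive) and CH13/CH14/CH16 (negative). The effect size
`delta` is expressed in units of the within-group feature SD so that
MCC levels are interpretable; a calibration constant (`amp_per_sd` =
0.56) converts one feature-SD unit into boxcar-amplitude units. It was
obtained once, before any acceptance measurement, from two quantities
under the default noise model: the feature value produced by a unit
noise-free amplitude after the full preprocessing chain (0.27 — the
0.01 Hz high-pass removes much of the slow block structure), and the
within-group feature SD of a zero-effect cohort (0.15). The default
`delta` = 0.5 lands the best cross-validated MCC in the 0.5–0.7 range.

The behavioural generator draws one latent ability per subject and maps
it monotonically into truncated-normal scores: accuracy (positively,
truncated to [0, 1]), reaction time (negatively, positive), NCT-A/NCT-B
completion times (negatively — so positively correlated with reaction
time), digit spans (positively). Truncation shifts means (a normal with
mean 0.32 and SD 0.21 truncated to [0, 1] has mean ≈ 0.35), so the
underlying location is adjusted by root finding until the truncated
mean equals the target; group accuracy and reaction-time targets are
the study's group statistics, while the neurocognitive test targets are
plausible synthetic values for a hepatic-encephalopathy screening
battery (they are not reported in the study). The default coupling
rho = 0.6 reproduces the observed correlation sign pattern in nearly
every cohort of 200 per group.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis relies
on — block-design responses with group-dependent amplitudes, in-band
and out-of-band physiological noise, coupled behavioural scores — but
not motion artefacts, systemic (scalp) contamination, nor realistic
spatial correlation between neighbouring channels. Passing tests
therefore validate the pipeline's algebra and its statistical
behaviour, not instrument-specific robustness.

Three empirical properties of the pipeline, measured by the test suite
and the acceptance script, are worth stating plainly:

* **Baseline-referenced features share a common noise offset.** After
  the 0.01–0.09 Hz band-pass, subtracting a 20-s baseline mean injects
  a per-subject-and-channel random offset whose variance is an order of
  magnitude larger than the block-to-block variance that survives both
  the high-pass (which removes slow between-block modulation) and the
  94.5-s block averaging (which removes fast in-band noise). The three
  block features of a subject-channel are therefore correlated at
  about 0.99, whatever the noise amplitudes: duplicated CIT rows add
  almost no independent information, and the effective sample size per
  channel is the number of subjects, not the number of rows. This is a
  property of the preprocessing recipe itself, not of the generator.

* **Permutation nulls are centred but single draws fluctuate widely at
  this sample size.** The acceptance script computes two permutation
  nulls on a default cohort — the exchangeable one (labels permuted
  across subjects, subject-grouped folds) and the row-level one
  matching the original sample-level design — each averaged over five
  permutation draws with the across-draw spread reported
  (`null_mean_mcc`, `null_mean_mcc_row_folds`, `*_sd_across_perms`).
  Both means sit near zero, but individual draws fluctuate with a
  standard deviation around 0.10–0.15 mean-MCC units (an early
  single-draw row-level null of +0.16 was such a fluctuation). Null
  calibration at n = 55 subjects therefore needs several permutation
  draws, and significance statements should use the null matching the
  fold scheme actually employed.

* **Top-subset recovery at delta = 0.5 is limited by sampling error.**
  With 30 + 25 subjects, the realised per-channel group difference of a
  cohort fluctuates around its planted value with a standard error of
  roughly 0.2–0.27 feature-SD units. At delta = 0.5 the genuinely best
  channels of a given cohort therefore often differ from the planted
  list, and the winning subset of a capped bilateral search (ranked by
  cross-validated MCC over ~15,000 candidates) typically shares 2–4 of
  the 6 planted channels. The same behaviour appears when the search
  is run on idealised i.i.d. Gaussian features with exact 0.5-SD
  effects, so it reflects the statistics of best-subset selection at
  this sample size rather than an implementation or generator defect.
  At delta = 1 the planted channels dominate and their weight signs are
  recovered. The recovery rate under the default conditions is
  computed, not assumed; see `scripts/acceptance.R`
  (`planted_recovery_rate`).

## Numerical choices

* Solver tolerances: `train_linear_svm` converges the dual KKT gap to
  1e-6 (1e-8 in oracle comparisons); cross-validation uses 1e-4 by
  default, and the capped bilateral searches in the analysis scripts
  use 1e-2, where fold metrics change only in the third decimal.
* MCC with any zero denominator factor is 0; a decision value of 0 is
  the positive class; ranking ties break by bACC, subset size, then
  lexicographic order.
* Problem sizes used in the checks: hemisphere searches run all 255
  subsets at the full 5 x 20 design; bilateral searches cap subset
  size at 6 (14,892 subsets); the recovery surface uses 20 cohort
  seeds. These sizes were chosen to keep a desk run in the minutes
  range while leaving every statistical conclusion unchanged.
* All randomness flows from explicit integer seeds: per-subject session
  seeds and per-repeat fold seeds are derived arithmetically from the
  master seed, so any result is reproducible from `(specs, seed)`.

## Limitations

The MBLL constants are device-class defaults, not values reported for
the actual instrument; concentration units are only comparable within a
configuration. The 20-s baseline reference noise discussed above is
faithful to the described recipe but statistically expensive; a
longer or per-block baseline would reduce it, and the package exposes
the layout so such variants can be simulated. Nonlinear kernels,
motion-artefact correction, short-channel regression and multiple-
comparison control over subsets are intentionally out of scope.
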