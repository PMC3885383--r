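---
title: "Methods: band-power seizure forecasting and its chance-predictor validation"
author: "pibcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-power seizure forecasting and its chance-predictor validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibcast)
```

## The forecasting problem

Long-term intracranial EEG (iEEG) monitoring makes it possible to ask
whether seizures are preceded by a detectable physiological state — a
*pre-ictal* state — or whether they strike at random. `pibcast`
implements a complete, testable version of the standard band-power
forecasting analysis for continuous multichannel recordings spanning
weeks to months:

1. **Features.** The common-average-referenced record is cut into
   non-overlapping 60 s blocks. Each block of each channel is Fourier
   transformed and periodogram power is summed over six canonical bands
   (delta 0.1–4, theta 4–8, alpha 8–12, beta 12–30, low gamma 30–70,
   high gamma 70–180 Hz), giving one *power-in-band* (PIB) feature per
   (channel, band) — 96 features for a 16-channel record.
2. **Labels.** Blocks whose start falls within the 90 minutes before a
   seizure onset are labeled pre-ictal; blocks overlapping a seizure are
   excluded; everything else is inter-ictal.
3. **Classifier.** A logistic regression on 10 features chosen by greedy
   forward selection estimates a per-block seizure risk in [0, 1].
   Everything is done under contiguous (blocked) 10-fold
   cross-validation so that no test block influences selection, scaling,
   or weights.
4. **Warnings.** Blocks whose out-of-fold risk exceeds a threshold open
   a 90 min warning; overlapping warnings merge into single
   variable-duration warnings. The threshold is calibrated per fold, on
   training risks only, so that time in warning (TIW) matches a target
   proportion (0.1–0.5 of the record).
5. **Scoring.** A seizure is forecast (true positive) if a warning both
   covers its onset and began at least 5 minutes earlier; a warning
   containing no onset is a false positive.
6. **Validation.** Sensitivity is compared against a Poisson-process
   chance predictor matched on realized TIW, persistence, and horizon;
   a one-sided Monte-Carlo p-value below 0.05 is the evidence threshold
   for forecasting beyond chance.

## Conventions and numerical choices

* **Time.** All times are seconds from record start; every interval —
  blocks, pre-ictal windows, ictal spans, warnings — is half-open
  `[start, end)`. Shared band edges (4, 8, 12, 30, 70 Hz) belong to the
  upper band under the same convention, which makes frequency-bin
  assignment over [0.1, 180) Hz exhaustive and exclusive.
* **Periodogram.** Blocks are mean-removed; no taper, no overlap. Powers
  are normalized so the sum over all positive-frequency bins equals the
  block variance in µV² (Parseval). The DC bin and bins at or above
  180 Hz contribute to no feature.
* **Feature transform.** Classifiers see
  `log10(PIB + eps)` standardized with training-fold mean and standard
  deviation; `eps` is the smallest positive normalized double, a guard
  against exact zeros (an all-zero block is already degenerate). Spectral
  power is scale-family distributed and heavy-tailed; logistic
  regression on raw power is numerically fragile.
* **Fit.** The logistic fitter maximizes the Bernoulli likelihood with a
  small ridge penalty (default `1e-4` on standardized features,
  intercept unpenalized) by Newton iterations with step halving. The
  ridge keeps separable steps finite during forward selection; at
  negligible penalty the fit agrees with `glm` to ~1e-6 (verified in the
  test suite).
* **Forward selection.** The selection criterion is mean out-of-fold AUC
  over a contiguous 5-fold inner split of the training rows, ties broken
  to the lowest column index. If every pre-ictal block of a training
  split sits in one contiguous stretch, no inner fold carries both
  classes on both sides; selection then falls back to in-sample AUC with
  a warning rather than abandoning the fold.
* **Threshold calibration.** The threshold is chosen from the sorted
  unique training risks by bisection over the monotone, stepwise
  TIW-versus-threshold curve; exact ties go to the larger threshold
  (less warning). Realized calibration error is reported, not enforced —
  the warning grid is discrete, so the match is approximate by nature.
  If all training risks are equal the threshold is placed at that value
  (no warnings) and a warning is raised.
* **Warnings and gaps.** Warnings run on wall-clock time and may span
  invalid-data gaps — a deployed device cannot retract a warning — and
  the TIW denominator is the full record span.
* **Fold geometry.** Folds balance valid-block counts (not wall-clock
  time), so training data is equalized when gaps are uneven. Ictal
  blocks are excluded from training and testing rather than labeled
  inter-ictal (the literal alternative is available via
  `ictal_as_interictal`), because labeling them inter-ictal teaches the
  classifier seizure rather than pre-seizure signatures.
* **Lead seizures.** A seizure is *lead* when no other onset occurred in
  the preceding 4 hours (onset-to-onset; the catalog has no reliable
  offsets for this purpose in general). Restricting sensitivity to lead
  seizures removes most of the benefit a forecaster gets from seizure
  clustering.

## The chance predictor

The null model triggers warning onsets from a homogeneous Poisson
process and applies the *same* persistence, merging, and horizon rules
as the candidate. Matching total time in warning fixes specificity: with
rate `lambda = -log(1 - TIW) / tau`, the Boolean-model coverage of
merged `tau`-length warnings is exactly TIW in expectation (onsets are
drawn on `[-tau, span)` so coverage is stationary over the whole
record). The per-seizure analytic hit probability
`1 - exp(-lambda (tau - h))` is exact for an isolated seizure and
reduces to TIW at `h = 0`; it ignores merging and clustering, so the
package's primary p-value is Monte-Carlo: `n_mc` chance warning sets are
scored against the *fixed observed* seizure times (preserving their
clustering), and

```
p = (1 + #{S_chance >= S_obs}) / (1 + n_mc)
```

one-sided, add-one to avoid `p = 0`. Because sensitivity is a discrete
statistic, ties make this estimator conservative: in null
self-consistency simulations the rejection rate at the 0.05 level runs
at roughly 2–4% rather than 5%, and the mean null p-value sits slightly
above 0.5. This is the standard, safe direction of error for a validity
claim. How published analyses "adjusted" sensitivities for chance
performance is not uniquely determined, so both adjusted forms — the
difference `S_obs - mean(S_chance)` and the normalized
`(S_obs - mean(S_chance)) / (1 - mean(S_chance))` — are reported
alongside the raw sensitivity.

## A cross-validation artifact worth knowing about

Pooling out-of-fold risks across contiguous folds and computing one
global AUC is *biased below 0.5 under the null* whenever seizures — and
with them pre-ictal blocks — are unevenly distributed over folds: a fold
holding many pre-ictal blocks was trained with fewer positives, so its
model has a lower intercept and scores *all* its test blocks (including
the positives) lower than other folds' models score theirs. The package
therefore assesses discrimination as the mean of per-fold AUCs, and the
forecasting path is immune by construction: each fold's warnings come
from its own model with its own calibrated threshold.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, at two levels.

**Seizure times** follow a Poisson cluster (Neyman–Scott-like) process:
cluster-initiating lead events arrive homogeneously at `lead_rate` per
day, cluster sizes are geometric with mean `cluster_size_mean`, and
intra-cluster onset gaps are log-normal with median
`intra_gap_median_s`. The defaults — 197 days, 5/197 leads per day, mean
cluster size 5.4, 30 min median gap, 60 s ictal duration — echo a
months-long canine record whose 27 seizures fell into 5 clusters; no
generative inter-seizure model is published for such data, so the
cluster process was chosen as the simplest mechanism with interpretable
knobs that reproduces clustering. Expected totals satisfy
`E[count] ~ lead_rate * days * cluster_size_mean` (verified by
simulation).

**Features** can be synthesized directly (months of blocks in seconds):
baseline `log10` PIB vectors are stationary Gaussians (sd 0.4 log10
units around a 1.5 log10-µV² baseline, optionally equicorrelated), and
inside pre-ictal windows the designated (channel, band) log-means shift
by `log10(effect)` — multiplicative on power, as befits a scale-family
quantity — either as a step (default; it matches the homogeneous
labeling window) or linearly ramped to onset. Invalid data arrives as
runs covering `gap_fraction` of the grid (default 5%; published plots
show gaps but not their budget). Raw signals (for short segments, with a
sample-count guard) are `1/f^alpha` noise plus band-limited sinusoids
whose amplitudes scale by `sqrt(effect)` pre-ictally.

What the generator does **not** emulate: circadian and multi-day rhythms
in band power, seizure-rate periodicity, physiologic artifact morphology,
channel-specific noise floors, and temporal autocorrelation of the
feature baseline. Passing tests therefore demonstrate that the pipeline
recovers pre-ictal structure *of the assumed kind* and controls its
error rates under the stated null — not that any particular real record
is forecastable. The raw-signal and feature-level paths use different
distribution families by design (filtered Gaussian noise vs log-normal
blocks), so they are compared through recovered effect ratios rather
than distributional equality.

## Problem sizes used by the test and acceptance suites

Desk-scale versions of the study conditions keep the suites fast while
preserving the regime being tested: the end-to-end recovery runs use 30
days of 1-minute blocks, 2 channels (12 PIB features, 3 selected, inner
3-fold), about 20 clustered seizures, target TIW 0.3, and 99 chance
draws per p-value, over 20 seeds per regime; chance-coverage checks use
1000 draws over a 60-day span; the null self-consistency check uses 200
replicates of 499 draws against 60 isolated seizures over 30 days. The
months-long 16-channel default regime is exercised at the catalog level
(counts, clustering) and through the 96-feature extraction shape checks.

## Known limitations

* The EDF layer targets continuous, uniform-rate recordings; EDF+
  annotations are skipped rather than parsed into validity masks.
* `chance_sensitivity_analytic()` is exact only for isolated seizures
  and sparse warnings; the Monte-Carlo route is authoritative.
* With very few seizure clusters, cross-validated performance estimates
  are dominated by a handful of effective units; p-values remain valid
  (the chance predictor sees the same clustering) but power is low.
* Per-fold TIW calibration transfers the training threshold to the test
  fold; under strong non-stationarity the realized test TIW can drift
  from the target, and the achieved deviation is reported per fold.
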