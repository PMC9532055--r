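---
title: "Multiscale wavelet features for EEG pathology detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale wavelet features for EEG pathology detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpath)
```

## The problem

Screening a clinical scalp EEG as *normal* or *pathological* is the first
step of most EEG-based diagnostic workflows, is laborious to do by eye,
and suffers from modest inter-rater agreement.  eegpath implements an
automatic detector built on a deliberately compact, interpretable feature
set rather than an end-to-end neural network: wavelet sub-band statistics
of short windows, collapsed over time by a multi-scale
standard-deviation aggregation, fused with the patient's age, and
classified with ensemble trees.

## The pipeline

### Preprocessing

Clinical archives mix montages of 21-31 channels and several sampling
rates.  Every recording is reduced to the 21 standard 10-20 electrodes
(`standardMontage21()`), in a fixed order; labels such as `"EEG FP1-REF"`
are normalized before matching.  Recordings are resampled to 250 Hz with
polyphase rational resampling behind an anti-aliasing FIR low-pass, then
cut from time zero into 100 non-overlapping 5-second windows of 1250
samples; anything after 500 s is discarded.  No re-referencing, filtering
or artifact rejection is applied beyond the resampler's low-pass.  For
recordings shorter than 500 s the `policy = "available"` option keeps all
full windows instead (at least two, so the local aggregation has both
halves); the strict 100-window protocol is the default.

### Wavelet features

Each window is decomposed with a 5-level discrete wavelet transform using
the order-6 Symlet (sym6), an orthogonal, near-symmetric wavelet that is
standard for biomedical signals.  Boundary handling is half-sample
symmetric extension, so a length-$L$ window yields
$\lfloor (L + 11) / 2 \rfloor$ coefficients per branch (49/49/88/165 for
A5/D5/D4/D3 at $L = 1250$).  At 250 Hz the retained sub-bands map onto
the clinically informative rhythms:

| sub-band | range (Hz) | rhythm |
|---|---|---|
| A5 | 0–3.9 | delta |
| D5 | 3.9–7.8 | theta |
| D4 | 7.8–15.6 | alpha / low beta |
| D3 | 15.6–31.2 | beta |

D1 and D2 (31–125 Hz) are discarded as dominated by muscle and line
noise.  From each retained sub-band six statistics are computed: mean
(MV), mean absolute deviation about the mean
$\mathrm{MAD} = \tfrac1m \sum_i |x_i - u|$, standard deviation (SD), mean
absolute value (MAV), skewness and kurtosis — $6 \times 4 = 24$ features
per window.  Each 24-value vector is z-scored to zero mean and unit
variance, which removes inter-recording amplitude scale.

Conventions the literature leaves open were fixed once and are
switchable in `waveletConfig()`: SD and the z-scoring use the
*population* (divide-by-$m$) form; skewness is the moment ratio
$g_1 = m_3 / m_2^{3/2}$ and kurtosis the excess $g_2 = m_4/m_2^2 - 3$,
both bias-uncorrected, so a Gaussian sub-band scores 0 on both.
Zero-variance inputs are guarded: skewness and kurtosis are defined as 0
and a constant feature vector z-scores to all zeros, so silent or
clipped channels cannot inject non-finite values.  Feature order is
sub-band-major (A5, D5, D4, D3) with statistics ordered
(MV, MAD, SD, MAV, skew, kurt); the order is arbitrary but frozen,
because trained models fingerprint the column layout.

Normalization scope was a genuinely open choice: z-scoring *within* each
24-value vector (the default, matching the single-vector depiction of
the procedure) versus scaling each feature *across* the cohort.  Both
are implemented (`normalizationScope` in `featurizeCohort()`); the
per-vector default makes each recording self-contained — no training
statistics leak into test features.

### Multi-scale aggregation

A 21-channel recording yields a $21 \times 100 \times 24$ tensor —
50,400 values, highly redundant.  The aggregation collapses the segment
axis: for every (channel, feature) pair the standard deviation is taken
over the *front half* of the windows (1–50), the *rear half* (51–100),
and *all* windows, giving local and global descriptors of how the
feature fluctuates over the recording.  The result is flattened
channel-major — channel, then scale (front, rear, global), then feature
— to $21 \times 3 \times 24 = 1512$ values, and the patient age in years
is appended raw as entry 1513.  Age is left unscaled because the
downstream tree ensembles are insensitive to monotone transformations.
With an odd number of windows the front half takes the extra one.  The
four ablation variants (`buildFeatureVariant()`) reproduce this
construction with no aggregation (raw flatten, 50,401 values), global
only (505), local only (1009), and the full form (1513).

### Classification

Two backends cover the three published configurations
(`defaultModelSpecs()`): gradient-boosted trees fitted with xgboost —
680 rounds, depth 4, learning rate 0.0343 (the strongest configuration
and package default) or 150 rounds, depth 18, learning rate 0.0441 — and
a random forest fitted with ranger (43 trees, depth 18, gini,
$\sqrt{p}$ features per split; ranger is used because it supports the
depth cap directly).  All remaining settings stay at backend defaults;
no class weighting is applied even though typical cohorts are mildly
imbalanced.  Training is single-threaded and seeded, so identical data
and spec give bit-identical models.  The pathological class is positive
throughout: TP counts pathological recordings correctly flagged.

Evaluation offers a held-out test set (the primary protocol) and
stratified 10-fold cross-validation.  Stratification is a deliberate
stabilizing deviation from plain random partitioning: with ~100-row
cohorts it prevents single-class training folds.  Metrics are accuracy,
sensitivity, specificity and F1, computed exactly from the confusion
counts; a zero denominator yields `NA` with a warning, never a silent 0.
Percentages are reported at two decimals with round-half-even.

## The synthetic cohort generator

The reference corpora for this task are registration-gated, so the
package ships a seeded generator (`synthConfig()`, `generateCohort()`)
whose defaults define the package's study conditions: 21 channels,
520 s at 250 Hz (so the strict 100-window protocol applies with 20 s
discarded), ages uniform on 1–90 years for both classes.  Normal
recordings are 1/f-power ("pink") Gaussian background scaled to 15 µV
RMS plus a ~10 Hz alpha oscillation of 5 µV.  Pathological recordings
additionally (i) have their sub-4 Hz spectral power multiplied by 3 and
(ii) carry spike-and-slow-wave bursts — a sharp ~70 ms transient
followed by a ~350 ms slow half-wave, 40 µV nominal peak — at 6 bursts
per minute on a focal subset (C3, P3, O1, mirroring the left
central/parietal/occipital focus typical of epileptiform examples).
These values were chosen once as a moderate, clearly pathological
phenotype: slowing (excess delta) and epileptiform transients are the
two canonical abnormality classes a neurologist reports.

The generator emulates *spectral structure and transients only*.  It
does not model artifacts (eye blinks, EMG), non-stationary state changes
(drowsiness), inter-channel covariance beyond shared burst timing, or
any disease process.  Passing tests on synthetic cohorts therefore
demonstrates that the pipeline's machinery is correct and that it can
recover a known class-dependent signal — not that the published
real-data operating points transfer.  Ages are drawn identically for
both classes by default so the age feature carries no label information
in the benchmark; `ageShift` exists to create a controlled age-class
association when studying the age-fusion effect.

Determinism: every recording's RNG stream is derived from
`(cohort seed, recording index)` via a fixed integer recurrence, so
cohorts are bit-identical across calls and platforms and independent of
the caller's RNG state.

## Numerical choices and degenerate inputs

* DWT boundary mode is symmetric half-sample extension; coefficients
  were verified against an independent reference wavelet toolkit to
  ~1e-12 and the inverse transform reconstructs inputs to better than
  1e-8 relative error.
* The analysis step is implemented as one sparse operator per level
  (folding extension, convolution and dyadic downsampling), which keeps
  featurizing a full 21 x 100-window recording well under a second.
* Resampling reduces the rate ratio to lowest terms p/q, zero-stuffs by
  p, applies a 20·max(p,q)+1-tap FIR low-pass at the tighter Nyquist
  limit with symmetric edge padding and group-delay compensation, and
  keeps every q-th sample; output length is ⌊n·p/q⌋.
* Recordings already at the target rate bypass the resampler exactly.
* Too-short inputs fail loudly: strict segmentation requires 100 full
  windows, available segmentation at least 2; local aggregation refuses
  single-segment tensors; training refuses single-class label sets.
* Model/row layout mismatches are detected by a 32-bit FNV-1a
  fingerprint of the column-name sequence and refused.

## Benchmark problem sizes

The packaged acceptance analysis trains on a 60+60 synthetic cohort and
evaluates on an independently seeded 60+60 cohort at the full study
conditions (520 s, 21 channels), and runs the aggregation ablation on
the same split.  The unit-test suite exercises the identical code paths
on smaller cohorts (35-second recordings under the available policy)
chosen to keep the default test run fast; the full-scale conditions are
exercised in the acceptance tests.

## Known limitations

* The synthetic phenotype is easier than real pathology; held-out
  accuracies on it exceed the published real-data operating points and
  should not be compared to them.
* Only sym6 is shipped; other wavelets would need their filter pairs
  added.
* The EDF writer/reader covers plain continuous EDF with equal
  per-signal rates; EDF+ annotations and discontinuous records are out
  of scope.
* Exact replication of any published fitted model is impossible by
  construction (seeds and threading of the original trainings are
  unknown); the package instead guarantees internal reproducibility.
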