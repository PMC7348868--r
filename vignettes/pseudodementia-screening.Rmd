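---
title: "Methods: acoustic screening of pseudodementia against dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic screening of pseudodementia against dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Major depressive disorder in elderly patients can produce a reversible
cognitive impairment — pseudodementia — that mimics true dementia in a
clinical interview. `pseudovoice` implements a screening pipeline that
separates the two groups from interview speech alone: waveform
preprocessing, a fixed 108-dimension acoustic feature summary per session,
group statistics, and a three-phase machine-learning protocol
(unsupervised k-means, nested cross-validated SVMs with LASSO-vote feature
selection, and a transfer evaluation on a non-age-matched cohort).

Because clinical interview recordings cannot be distributed, the package
ships a synthetic cohort generator that reproduces the *statistical
structure* the analysis relies on, so every stage is testable end to end.

## Preprocessing

A recorded sample $X$ is an outlier when $X < Q_1 - 1.5\,\mathrm{IQR}$ or
$X > Q_3 + 1.5\,\mathrm{IQR}$ (strict inequalities; quartiles over the
whole recording, linear-interpolation "type 7" convention by default,
configurable). A natural cubic smoothing spline is then fitted to the
signal *without* the outliers, minimising

$$\sum_i (y_i - f(x_i))^2 + \lambda \int f''(t)^2\,dt .$$

Whether the spline only fills the outlier gaps or replaces the whole
signal was an open design point; the fit is dual-purpose (interpolation
*and* subtle noise removal), so full replacement is the default with
`replace_all = FALSE` as the interpolation-only option. The solver is the
Reinsch banded algorithm (O(n), implemented in C++) with knots at every
sample: knot-thinning smoothers cannot track a speech waveform at
near-interpolation fidelity. The default penalty $\lambda = 10^{-4}$ (in
sample-index units) behaves as a gentle low-pass near the Nyquist
frequency; on voiced test material it leaves more than 99.9% of signal
variance intact, matching the "subtle" intent. Spline residue smaller
than $10^{-10}$ on silent samples is clamped back to exact zero so that
silence stays silence.

Amplitude is then rescaled so the peak absolute value is 0.99, and exact
zero runs at the recording edges are trimmed. Interior silence is
deliberately kept — pauses between dialogue turns are potentially
informative. Trimming only removes exact zeros, so it commutes with the
rescaling (asserted in the tests).

## Features

36 frame-level features are computed on non-overlapping 10 ms windows
(160 samples at 16 kHz): pitch, harmonics-to-noise ratio (HNR),
zero-crossing rate, 14 mel-frequency and 14 gammatone cepstral
coefficients, power-spectrum mean and median frequency, signal energy
$\sigma/\mu$, spectral centroid and spectral rolloff. Each is summarised
by mean, median and sample SD (the $n-1$ convention throughout) over the
session, giving the 108-dimension vector. A 600 s session yields exactly
60,000 frames; the trailing partial frame is dropped.

Choices the source formulas leave open, all exposed in
`feature_config()`:

* **Cepstra.** 32 bands (triangular mel filters on 0–8 kHz; ERB-spaced
  fourth-order gammatone magnitude responses on 50 Hz–8 kHz sampled on
  the FFT bins), Hamming window, orthonormal DCT-II, 14 coefficients
  *including* the 0th, log floor $10^{-10}$. The plain spectral moments
  use the unwindowed periodogram, which keeps the Parseval identity exact.
* **Rolloff** threshold $k = 95$%.
* **Pitch/HNR context.** A 10 ms frame cannot hold one period of a low
  f0, so pitch and HNR use a 40 ms context centred on each 10 ms hop
  (the hop stays 10 ms, so frame counts agree across features). The
  estimator is the normalized autocorrelation peak over 60–400 Hz with
  the unbiased lag correction $n/(n-\tau)$; among lags within 0.01 of the
  global peak the smallest is taken (octave-error guard), frames with
  peak below 0.3 are unvoiced (pitch undefined),
  $\mathrm{HNR} = 10\log_{10}(r_{max}/(1-r_{max}))$.
* **Undefined values** (unvoiced pitch, $|\mu| < 10^{-12}$ energy,
  silent-frame spectral moments) are excluded from the summaries rather
  than zero-filled, to avoid sentinel bias. With the default full band,
  mean frequency and spectral centroid coincide — both are kept because
  the feature list defines them separately and the band edges of the
  centroid are configurable.

## Cohort filtering

Inclusion (inclusive bounds): symptomatic dementia is MMSE $\le 23$ with
GDS $\le 5$; symptomatic depression is HAMD17 $\ge 8$; sessions at least
10 min; the age-matched analysis band is 57–84 years. The transfer test
set applies the same symptomatic rules at age $\ge 85$ (dementia) or
$\le 56$ (depression). Every session lands in exactly one of
age-matched / transfer / excluded-with-reason; duration is measured after
preprocessing. Sessions are treated as independent datasets (the study's
own reading); a subject-grouped flag is carried for leakage-aware
variants.

## LASSO-vote feature selection

Within each outer training set, a single stratified 10-fold inner
partition serves both selection and tuning. On each inner training
subset, predictors are standardized (training statistics only) and a
LASSO

$$\min_{\alpha,\beta}\; \frac{1}{2N}\sum_i\Big(y_i - \alpha -
  \sum_j \beta_j x_{ij}\Big)^2 + \lambda \sum_j |\beta_j|$$

is fitted by exact cyclic coordinate descent at a penalty *just below*
the largest value admitting a nonnull model,
$\lambda_{max} = \max_j |\sum_i x_{ij}(y_i - \bar y)|/N$. Infinitesimally
below that threshold the single entering coefficient is numerically zero
and the 0.01 marking rule would be vacuous, so the fit is placed at
`lambda_scale * lambda_max` with `lambda_scale = 0.9` by default: close
enough to the threshold that the model stays very sparse, far enough
that entering coefficients are measurable against the cutoff. Model
performance is deliberately not consulted at this step, and there is no
cross-validated $\lambda$ selection.

A feature is *marked* in an inner fold when $|\beta_j| < 0.01$ (strict;
the absolute-value reading — sign is arbitrary under 0/1 label coding — a
signed variant is available) and *removed* only when marked in all 10
inner folds. If the vote removes everything (pure-noise data), the fold
falls back to the full feature set rather than fitting an empty model;
`vote_select()` itself still errors on the degenerate case so the
condition is never silent.

## Models

* **Phase 1**: k-means, $k = 2$, squared Euclidean distance (Lloyd
  iterations, 50 seeded restarts, best inertia kept) on standardized
  features. Cluster labels carry no class meaning, so the
  accuracy-maximizing cluster-to-class mapping is used (majority-vote
  mapping available).
* **Phase 2**: stratified nested 10-fold CV. Folds are dealt round-robin
  within class, continuing across classes so fold sizes differ by at most
  one (89/88 sessions give folds of 17–18 with 8–9 per class). Per outer
  fold: LASSO-vote selection, then an inner-CV grid search over the cost
  $C$ (and $\gamma$ for the RBF kernel) with first-in-grid tie-breaking,
  then a soft-margin SVM (linear, 3rd-degree polynomial, or RBF) on the
  standardized retained features. The printed grid range of the source
  protocol is typographically garbled ("11000 to 1000"); it is read as
  1/1000 to 1000 and the default grid is $\{10^{-3},\dots,10^3\}$,
  configurable. Standardization, $\lambda_{max}$, marking and tuning
  never see the outer test fold; the tests assert this by perturbing a
  test fold and checking the fold's selection, hyperparameters and
  training metrics are bit-identical.
* **Phase 3**: a final SVM is trained on the whole age-matched set using
  the features retained in at least one outer fold of phase 2 (i.e. only
  *completely rejected* features are dropped), then evaluated once on the
  transfer cohort with frozen standardization. Feature contributions are
  the absolute linear-SVM coefficients on the standardized scale, sorted
  descending.

## Metrics

From TP/FP/TN/FN (depression = class 1 = positive): accuracy, TPR, TNR,
PPV, NPV, F1, Cohen's kappa via
$\mathrm{EXP} = [(TP{+}FP)(TP{+}FN) + (TN{+}FN)(TN{+}FP)]/\mathrm{total}^2$,
and Matthews correlation with the four-factor denominator. Ratios with a
zero denominator are reported as missing, never silently zero — except
MCC, which takes the conventional value 0 with a degeneracy flag.
Reporting scale is percent at one decimal; internal values keep full
precision. Published confusion summaries are reconstructed by
nearest-integer rounding of TPR/TNR against the class sizes; all
reconstructed cells reproduce to one decimal except one PPV cell that
lands one rounding step away (58.39 vs a printed 58.3), which the
reconstruction cannot resolve further.

## The synthetic cohort generator

Each subject's voice is a source-filter model: a glottal pulse train at
$f_0 \sim U(100, 250)$ Hz (distribution shared across classes), a
one-pole spectral-tilt filter, two formant resonators (F1 class-shifted,
F2 random), a DC-blocking high-pass (as any real recording chain has —
this also keeps the $\sigma/\mu$ energy feature decoupled from tilt),
white noise at 20–28 dB SNR, and a random overall peak in 0.1–0.9 so
energy and loudness overlap across classes. Class structure lives
entirely in two envelope latents — spectral tilt and F1 position — whose
class means differ by `class_separation` within-class SDs (default 3, the
"strong signal" regime; 0 gives the exchangeable null). Clinical scores
are linear in the combined envelope latent plus noise: HAMD17 with a
negative loading and MMSE with a positive one, targeted at $|r| = 0.3$;
the realized feature-level correlation on the centroid probe is about
0.24, inside the weak-to-moderate band the screening setting exhibits.
Demographics follow the age-matched clinical cohort (depression
67.8 ± 7.1 years, 83.3% female; dementia 77.0 ± 7.5 years, 72.4%
female), clamped to the 57–84 band so a default cohort passes its own
inclusion filter.

Default sessions are 30 s (the clinical sessions are ≥ 600 s; the frame
arithmetic is scale-exact, so only summary noise changes). Multiple
sessions per subject share voice parameters with small jitter. Identical
spec and seed give a byte-identical corpus, including written WAV files.

What the generator does *not* emulate: phonetics, language content,
dialogue structure, room acoustics, clinician crosstalk. Passing tests
therefore demonstrate that the pipeline recovers class structure placed
in the spectral envelope under realistic noise — not that it screens real
patients.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
90 + 90-session cohorts of 30 s audio (both the null and the separated
regime), 1,000 label permutations for the family-wise-error check, and
exhaustive or 100-draw oracle sweeps for the numeric kernels; smaller
15–30-session cohorts back the invariant checks. These sizes were chosen
as the smallest at which the statistical claims are sharp (binomial 95%
bands, sign tests at $|r|\approx 0.24$). Degenerate inputs are handled
explicitly: all-zero signals refuse normalization, all-masked signals
refuse interpolation, k-means on fewer distinct points than clusters
returns one cluster, zero-variance features propagate NA rather than
fabricate correlations, and grid-search ties resolve to the earliest
entry deterministically.

## Known limitations

* The $\sigma/\mu$ "signal energy" is numerically wild on near-zero-mean
  frames; the guard excludes such frames, so its summaries are stable but
  heavy-tailed — faithful to the printed formula rather than to common
  practice (RMS energy).
* Pitch tracking is a plain autocorrelation peak; occasional octave
  errors survive the guard in noisy frames. In this design pitch carries
  no class signal, so this costs nothing downstream.
* The LASSO marking penalty sits near $\lambda_{max}$, so retained sets
  are very sparse (typically 3–8 features per fold on synthetic
  cohorts) — sparser than on the clinical data, where 82 of 108 features
  survived. The vote rule, not the sparsity level, is the contract.
* Nested CV treats sessions as independent, mirroring the study design;
  with multiple sessions per subject this is optimistic, and the
  subject-grouped option exists for stricter evaluation.
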