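---
title: "Acoustic analysis of continuous-flow LVAD sound: model, features, and classification"
author: "lvadsound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic analysis of continuous-flow LVAD sound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvadsound)
```

## The problem

A continuous-flow left ventricular assist device (LVAD) is an implanted
rotary pump. Its impeller, turning at 8,000–12,000 rpm, radiates a tonal
sound whose fundamental sits at the rotational frequency `rpm/60` — 10,000
rpm corresponds to a 167 Hz peak — together with integer harmonics and
broadband non-harmonic noise. Because the pump couples hydraulically to the
circulation, physiology modulates this tone: the cardiac cycle
frequency-modulates the fundamental (the load on the impeller varies beat by
beat), and respiration amplitude-modulates the whole signal. Some devices
additionally run an intermittent-low-speed (ILS) protocol — nominally
dropping to 7,000 rpm for 8 s every 64 s — so the native aortic valve can
open.

Significant aortic regurgitation (AR), a backward leak through the aortic
valve, is a common late complication. It changes pump loading and therefore
the sound: the relative prominence of the first harmonic, the rotational
speed reached during ILS, and the beat-to-beat fluctuation of the sound's
amplitude all shift. `lvadsound` implements the full analysis chain that
exploits this: time–frequency decomposition of a chest-wall recording,
extraction of 19 acoustic features, and a feature-selection plus
classification stage that flags recordings consistent with significant AR.

Because no patient recordings are publicly available, the package ships a
synthetic generator that plants every parameter of the acoustic model with
exhaustive ground truth. All quantitative claims made by the test suite are
claims about recovery of planted structure, not about patients; see
"What the synthetic data do and do not show" below.

## The signal model

`simulate_recording()` synthesizes

$$x(t) = e(t)\sum_{k=1}^{K} A_k \sin\!\big(k\,\phi(t) + \varphi_k\big) + \nu(t),
\qquad \phi(t) = 2\pi \int_0^t f_0(u)\,du,$$

with

* $f_0(t) = \mathrm{rpm}(t)/60 + D(t)\sin(2\pi f_c t + \varphi_c)$ — the
  fundamental, frequency-modulated at the cardiac rate $f_c$ (bpm/60) with
  peak deviation $D$ (Hz). Modulating the phase integral rather than
  multiplying frequencies keeps phase continuous through speed changes.
* $\mathrm{rpm}(t)$ — the speed command: `normal_rpm` except during ILS
  windows at `ils_rpm`, convolved with a 1 s Hann kernel. Real pumps cannot
  step speed instantaneously; the symmetric kernel also makes the 50 %
  crossing of the ramp coincide exactly with the commanded window boundary,
  so ground truth and an unbiased detector agree by construction.
* $e(t) = 1 + m_r \sin(2\pi f_r t) + g(t)\, m_i \sin(2\pi f_c t)$ —
  respiratory amplitude modulation of depth $m_r$ at the respiratory rate
  $f_r$, plus an ILS-gated cardiac-rate amplitude modulation of depth $m_i$
  ($g(t)$ is the smoothed ILS activation). The latter encodes the stronger
  beat-to-beat loading fluctuation while the native valve opens.
* $\nu(t)$ — Gaussian noise confined to the three bands defined relative to
  the fundamental (below it; between it and the second harmonic; above the
  second harmonic), synthesized in the frequency domain and calibrated so
  the analyzer recovers a requested mean level in arbitrary units.

Defaults (10,000 rpm, ILS 7000 rpm / 8 s / 64 s, 84 bpm with 4.2 Hz
deviation, 20 breaths/min with 11 % depth, harmonic amplitudes 1 : 0.13 :
0.16, band noise 6.6 / 4.4 / 1.2 a.u., 40 kHz sampling) reproduce the
reference cohort's mean feature values. Cohort generators
(`simulate_cohort()`, `sample_cohort_params()`) draw per-recording
parameters from per-class truncated normal distributions whose means and
spreads are the reference AR-negative and AR-positive cohort statistics
(`feature_class_stats()`); four canonical AR shifts — lower first-harmonic
relative amplitude, lower ILS speed, smaller ILS amplitude-variation, larger
normal-rotation amplitude-variation — are each independently switchable and
jointly scaled by an `effect_multiplier` (0 = identical classes; the
multiplier interpolates both class means and class spreads, so the null is
exact).

One modeling caveat: after normalization to arbitrary units the first
harmonic's own a.u. amplitude is nearly scale-free (it *is* the
normalization maximum, up to modulation depth), so the audio-level
first-harmonic shift manifests mostly as a complementary shift of the other
components. The feature-level cohort generator
(`simulate_feature_table()`), which draws the 19 features directly from the
per-class distributions, plants that contrast exactly and is the tool used
for selection and classification experiments at scale.

## Time–frequency analysis

`gabor_scalogram()` implements an analytic Gabor filter bank: each channel
is Gaussian in the frequency domain, centered on a grid frequency $f$ with
constant-Q width FWHM $= f/16.7$ — about 10 Hz at 167 Hz. That width
separates the fundamental from its ±1.4 Hz cardiac sidebands (they appear
as ridge *fluctuation*, not as distinct ridges) while keeping the temporal
resolution ($\sigma_t = 1/2\pi\sigma_f \approx$ 37 ms at 167 Hz) fast enough
to follow the modulation. The default grid is logarithmic, 48 bins/octave
over 20–2000 Hz (~320 channels); amplitudes are calibrated so a unit tone
yields a unit ridge. Channels are evaluated from one FFT of the whole
recording followed by short band-limited inverse FFTs, so a two-minute
recording is mapped in a few seconds. The first and last wavelet-support
half-widths (`edge_sec()`, ≈1 s with the default grid) are excluded from all
feature statistics.

`normalize_amplitude()` expresses the map as a percentage of its largest
value within a chosen window (arbitrary units, a.u.; default window = full
extent minus edges). Recorded amplitude depends on stethoscope placement, so
every amplitude-type feature is defined on this scale; the test suite checks
end-to-end invariance of all 19 features under positive rescaling of the
waveform.

## Tracking, segmentation and features

`track_harmonic()` picks the per-frame amplitude argmax inside the
harmonic's search band and refines it by parabolic interpolation of the
log-amplitude across the three neighboring channels — exact for the Gaussian
channel profile, giving sub-grid frequency and amplitude estimates. Higher
harmonics are tracked anchored to the fundamental (`k × f1(t) ± 8 %`), which
prevents the third-harmonic tracker from locking onto a strong second
harmonic. Frames with no peak above the floor are explicit gaps.

`detect_ils()` labels ILS operation: frames whose fundamental sits below the
midpoint between the protocol ILS frequency and the recording's *own*
normal-operation frequency (upper quartile of the track, floored at the
configured minimum normal speed) for ≥ 2 s, with boundaries refined to the
50 % crossing between the segment's plateau and the surrounding normal
frequency. The data-driven midpoint matters because measured ILS speeds
scatter several hundred rpm around the commanded 7,000; a fixed threshold
midway to the slowest normal speed would miss slow-drop recordings. Ramps
(±0.5 s) are labeled `transition` and excluded from both normal and ILS
statistics. A recording longer than one ILS period with no detected window
warns and returns an all-normal labeling — real recordings can simply miss
the window, and the three ILS features are then flagged missing rather than
fabricated.

Fluctuation features use `fluctuation_spectrum()`: mean-detrended,
Hann-windowed, zero-padded FFT of a track component, scaled so a sinusoidal
modulation of peak deviation $D$ yields a spectral peak of amplitude $D$.
"Amplitude of frequency variation" and "amplitude of amplitude variation"
are defined as the dominant non-DC peak amplitude of that spectrum (units Hz
and a.u.) — matching the observation that these spectra show a strong single
peak — with the search band starting at three cycles per analysis window
(3/T). That lower edge is what reconciles the two amplitude-variation
features: a ≥ 28 s normal window resolves the respiratory peak
(0.33 Hz), so the normal-rotation amplitude-variation reads respiratory
modulation, while an 8 s ILS window cannot (3/8 s = 0.375 Hz ≥ 0.33 Hz), so
the ILS amplitude-variation reads the cardiac-rate loading fluctuation.
The heart rate is 60× the dominant peak of the fundamental's
frequency-fluctuation spectrum in 0.7–3 Hz — widened from the typical
1–1.5 Hz description so bradycardic and tachycardic patients are not
clipped — and the respiratory rate 60× the sub-0.5 Hz peak of the
amplitude-fluctuation spectrum, each flagged missing below a 3× prominence
threshold. The ILS fluctuation window (8 s minus 0.6 s ramp trim per side)
is accepted down to 4 s; the 10 s default minimum applies to spectra that
must resolve sub-0.1 Hz structure.

Non-harmonic band amplitudes are map means over the low/middle/high bands
with ±1 FWHM neighborhoods around every harmonic excised (otherwise ridge
leakage, ~6 a.u. just outside a peak, would masquerade as noise).
Rotational-speed features are acoustic: 60 × the median tracked fundamental
over normal (respectively ILS-interior) frames. The full catalogue is
`feature_catalogue()`; extraction returns exactly 19 values with explicit
missing flags, and an unanalyzable recording raises a structured error
rather than a partial result.

### Known numerical biases

The wavelet's temporal response low-passes the ridge tracks: a 1.4 Hz
modulation of the 167 Hz fundamental is recovered with ≈ 95 % of its true
deviation ($\exp(-(2\pi f_m \sigma_t)^2/2)$). This ~5 % bias is left
uncorrected — it is well inside the 10 % relative tolerance the recovery
suite enforces, identical across recordings, and therefore irrelevant to
classification. Parabolic ridge interpolation is exact for Gaussian
profiles, so frequency estimates carry no comparable bias (ILS and normal
speed recover within a few rpm of the planted values).

## Feature selection and classification

The selection pipeline follows a filter + wrapper design, scored throughout
by leave-one-out misclassification of a linear discriminant:

1. **Rankings.** `rank_by_ttest()` (unpaired pooled-variance t-test,
   ascending p; ties broken by catalogue order), `rank_by_gini()`
   (random-forest mean decrease in Gini impurity), and optionally
   `rank_by_nca()` (diagonal neighborhood component analysis, off by
   default).
2. **Filter.** `filter_select()` adds features in rank order and keeps the
   earliest prefix minimizing LOOCV error. The discriminant used here is an
   in-package pooled-covariance LDA with automatic diagonal shrinkage on
   singular covariance and exact rank-one leave-one-out downdates — LOOCV
   costs one small solve per sample, which is what makes 50-replicate
   property tests affordable. It is verified against a brute-force
   `MASS::lda` refit oracle in the tests.
3. **Wrapper.** `wrapper_select()` runs greedy forward selection within the
   filter subset; the best single feature is always taken, further features
   only on strict LOOCV improvement, ties resolved by catalogue order.

`benchmark_classifiers()` evaluates 9 classifiers — linear discriminant
analysis, distance-weighted 5-NN, Gaussian naive Bayes, kernel
(density-estimate) naive Bayes, random forest, linear and RBF support
vector machines, a CV-pruned decision tree, and an ensemble of 100 bagged
trees (AdaBoost available as an option) — on a stratified 75/25 split.
Median imputation and z-scaling are fitted on the training rows only;
hyper-parameters are tuned on training data (LOOCV for the SVMs, tenfold
stratified CV for the random forest, internal tenfold pruning for the
tree); metrics (accuracy, rank-statistic AUC with midrank ties, TPR, TNR;
positive class = AR present) come from the untouched test rows.
`run_analyze()` draws the split *first* and runs the whole selection
pipeline on the training rows, so no test information reaches ranking,
imputation, scaling or tuning — a leakage canary (a feature informative only
in test rows) is part of the test suite.

## What the synthetic data do and do not show

The generator emulates the acoustic *structure* of pump sound — harmonic
stack, physiologic modulations, ILS protocol, banded noise — and the
measured per-class feature distributions. It does not emulate chest-wall
transfer functions, transient artifacts (movement, speech, stethoscope
repositioning), non-Gaussian or non-stationary noise, within-patient
correlation of repeated recordings, or any hemodynamics of regurgitant flow.
Passing tests therefore demonstrate that the pipeline recovers planted
acoustic structure at realistic signal-to-noise ratios and that the
selection/classification machinery is statistically sound (chance-level null
AUC, monotone response to effect size, no train/test leakage). They do not
validate clinical performance; the headline clinical numbers reported for
this approach (ensemble accuracy 0.91, AUC 0.73 on 245 patient recordings)
require the original recordings, which were never deposited.

## Problem sizes and numerical choices

Chosen to keep the default test run inside a few minutes on one core, and
stated here as the package's own study design:

* Single-recording checks use one 128 s protocol recording (two full ILS
  cycles); physiologic-recovery uses a 20-recording cohort of 66 s
  recordings planted at the reference means; parameter-spread recovery uses
  a 12-recording cohort with full between-recording variation.
* Selection-recovery properties use 50 replicates of 160-recording feature
  tables with three planted informative features (2.2 SD shifts), requiring
  ≥ 80 % recovery of all three.
* Permutation-null and effect-monotonicity properties use study-sized
  (n = 245) feature tables at prevalence 0.25 (a 61-row test split with the
  study's native 10.6 % prevalence leaves ~6 positives — too few for a
  stable AUC), 20 seeds per condition, ensemble classifier; the null is
  computed at the identical configuration.
* Tie-breaks everywhere follow feature catalogue order; all stochastic steps
  take explicit seeds, and per-recording sub-seeds derive deterministically
  from the root seed.

## A worked example

```{r example, eval = FALSE}
library(lvadsound)

# one protocol recording with planted ground truth
p <- pump_sound_params(normal_rpm = 10033, seed = 11)
sim <- simulate_recording(p)
fv <- extract_features(sim$recording)
fv$values[c("rpm_normal", "rpm_ils", "heart_rate", "resp_rate")]

# a labeled feature-level cohort and the full modeling stage
tab <- simulate_feature_table(245, ar_prevalence = 26 / 245, seed = 1)
res <- run_analyze(tab, seed = 1, tune = FALSE)
res$selection$wrapper_subset
res$report
```
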