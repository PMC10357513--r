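---
title: "Recognizing haptic-modulated emotions from EEG: models and methods"
author: "hapticEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing haptic-modulated emotions from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Affective haptics asks whether vibrotactile stimulation — here, a wearable
vibration vest worn while watching emotional film clips — modulates the
emotions a person experiences, and whether that modulation is measurable in
the EEG. The experimental design this package implements compares four
target emotions (joy, sadness, fear, neutral) under two vibration patterns:
a *fixed* pattern (each emotion has a set vibration frequency and intensity,
e.g. joy = 1.4 Hz pulses at 90% intensity) and an *adaptive* pattern whose
intensity follows the soundtrack volume, with a silence threshold gating the
rhythm. Vibration is applied only during the second half of each clip, so
every session yields a matched non-haptic/haptic pair of signal halves, and
the haptic effect can be quantified within subject as the change in emotion
decodability.

The pipeline is: simulate (or read) multichannel recordings → preprocess →
extract band-wise features → classify emotions per subject with a linear
SVM → compare haptic against non-haptic accuracy with paired statistics →
summarize spectra and scalp topographies.

## Why a synthetic-data generator

The recordings this design describes are not publicly deposited, so the
package ships a first-class generator that emulates the experiment's
statistical structure: 63 usable channels of a 64-channel 10–20 cap
(FCz reference, Fpz ground) at 1,000 Hz; 16 sessions per subject (four per
emotion), each a 5-s cue, a film clip, and a self-assessment/rest gap; both
haptic patterns presented for eight sessions (two per emotion, randomized);
50 Hz line interference; and frontal EOG-like blink bursts.

Each channel is a sum over the five canonical bands (delta 1–4, theta 4–8,
alpha 8–14, beta 14–31, gamma 31–50 Hz) of band-limited Gaussian noise,
synthesized by spectrally masking white noise — the minimal stationary model
under which band-power features carry the class signal. Per (band, channel
group) the variance is

\[ v = v_{\text{base}}(b)\, e^{j} \;+\; g^2\, s(b)\, v_{\text{base}}(b)\, d(e, b, \text{group})^2 , \]

where \(e^{j}\) is a per-session log-normal jitter shared within a
(group, band) cell (session-to-session nonstationarity), \(s(b)\) is the
band's discriminative variance share, \(d\) the emotion multiplier, and
\(g\) the *haptic separation gain* (\(g \ge 1\); applied only during the
haptic half, \(g = 1\) makes the two halves statistically exchangeable).
The profile concentrates class information in beta/gamma power of the
lateral temporal and prefrontal regions — joy activating temporal channels,
sadness prefrontal, fear intermediate, neutral inhibited — with a weak
alpha effect over parietal channels and no class information in delta/theta.
A hemispheric bias (joy left-dominant, sadness right-dominant) gives the
left–right pair differences their signal; without it, bilaterally symmetric
power would cancel in DASM exactly.

### What the generator does and does not emulate

It reproduces the *feature-level* statistics the analysis consumes: band
powers, their class structure, scalp localization, lateralization, session
nonstationarity, line noise, blinks. It does not model neural waveform
morphology, volume conduction, within-band 1/f slopes, or non-stationary
emotional dynamics within a clip. Passing tests therefore validate the
pipeline's machinery (filters, estimators, folding, statistics) and its
sensitivity/specificity to the modeled effects — not performance on real
recordings.

### Calibration of the default effect sizes

The defaults were calibrated once so that the evaluation reproduces the
*scale* of accuracies the emulated experiment reports — non-haptic gamma-DE
accuracy in the mid-80s, haptic in the mid-90s, a relative growth near
+8% — and were then frozen. Three parameters set that operating point:
`session_jitter_sd` (0.1) bounds the achievable accuracy under
session-grouped cross-validation, `disc_share` (0.5 in beta and gamma) sets
how far the non-haptic condition sits below that ceiling, and
`haptic_gain` (2) restores the haptic condition towards it (the gain enters
the variance quadratically). Delta/theta carry no class signal by
construction, so their accuracies sit at chance — unlike real recordings,
where residual information keeps them above chance; that discrepancy is
expected and documented rather than emulated.

## Preprocessing

The chain follows standard EEG practice: decimation from 1,000 to 200 Hz
(order-6 zero-phase Butterworth low-pass at 0.45 × the target rate, then
integer subsampling), a 50 Hz notch (order-2 band-stop, Q = 30), a 1–50 Hz
band-pass (order-4 Butterworth), optional seeded ICA artifact removal, and
common average re-referencing. All filters run forward–backward
(zero-phase). Two choices deserve note:

* **ICA.** No ICA implementation ships with the installed R stack, so the
  package provides a seeded symmetric FastICA (tanh contrast). Components
  whose absolute correlation with the frontal EOG proxy (Fp1/Fp2 average)
  exceeds 0.8 are zeroed. Manual component selection, as practiced with
  EEGLAB-era pipelines, is deliberately replaced by this reproducible
  criterion; the stage is off by default in the synthetic analyses (the
  generator's artifacts exist to exercise it in tests) and can be enabled
  with `ica = TRUE`.
* **Reference recovery.** The cap records against FCz, yet the
  frontal-posterior pair table includes FCz–CPz. After common-average
  re-referencing, FCz is recovered as the negated pre-average channel mean
  (the standard reference-recovery identity), so the pair is computable.
  Channel-wise feature tensors still use only the 63 data channels.
* **Baseline.** The 5 s before each clip is carried alongside each segment
  and used only in the topographic stage (baseline DE subtraction), not
  subtracted from the time series.

## Features

Per non-overlapping 1-s window (200 samples, Hanning-tapered, zero-padded
to a 256-point FFT):

* **PSD** — mean spectral energy over each band's bins (`lo <= f < hi`).
* **DE** — Gaussian differential entropy
  \(h = \tfrac12 \ln(2\pi e \hat\sigma^2)\) of the band-filtered window,
  in nats; natural log is used so the unit-variance constant
  \(\tfrac12\ln(2\pi e) \approx 1.4189\) holds exactly. The variance route
  (sample variance of the filtered window) is the primary estimator; the
  log-band-energy route is retained as an independent test oracle — the two
  agree affinely with \(R^2 > 0.99\) on stationary inputs.
* **DASM** — DE(left) − DE(right) over the 28 printed hemispheric pairs.
* **DCAU** — DE(frontal) − DE(posterior) over the 22 printed
  frontal-posterior pairs.

Zero-variance windows are floored at a configurable `var_floor` and
flagged. No temporal smoothing is applied to the feature series. Band rows
for classification are the five bands plus `"total"`, the all-band
concatenation (63 × 5 = 315 columns for DE). Each 1-s window is one
classification sample; per-session averaging would change absolute
accuracies substantially, and the window-level default is exposed rather
than hidden.

## Classification and evaluation

Per subject and grid cell (pattern × condition × feature × band): a
linear-kernel SVM (e1071/libsvm, C = 1, untuned, native one-vs-one
multiclass) evaluated by 4-fold cross-validation. Folds are *grouped by
session* — windows of one session never span the train/test split — and
class-balanced: the sessions of each class are spread across folds, and
every training fold must contain all four classes. With eight sessions per
(pattern, condition) cell this means two sessions per class, which is the
experiment's own constraint; a requirement of at least `k` sessions per
class would be unsatisfiable under the design, so the implementation
requires at least two per class and errors otherwise. Features are
standardized with training-fold statistics only. Session-grouped folding is
stricter than window-level shuffling (which leaks within-session
autocorrelation and inflates accuracy); this is a deliberate design choice
and the main reason absolute accuracies here should not be compared
naively against window-shuffled results.

## Statistics

Per (feature, band, pattern) cell across subjects: a two-sided paired
t-test on per-subject accuracies (haptic minus non-haptic, df = n − 1) and
the mean relative growth rate, computed per subject as
\((a_\text{hap} - a_\text{non}) / a_\text{non} \times 100\) and then
averaged. The growth aggregation is genuinely ambiguous in this design
(ratio-of-means vs mean-of-ratios differ); mean-of-per-subject-ratios is
used and documented. No multiple-testing correction is applied by default,
matching the design being emulated; `accuracy_stats(..., adjust = "holm")`
provides one.

## Spectral and topographic summaries

Time-frequency maps use a Morlet continuous wavelet transform (7 cycles,
30 log-spaced frequencies over 1–50 Hz, FFT convolution, unit-energy
kernels), averaged within non-overlapping 5-s windows and optionally over
channels. Topographies are window-mean DE minus window-mean baseline DE per
channel and band, averaged over sessions/subjects, with electrode positions
from the montage's azimuthal-equidistant projection; Gaussian
radial-basis interpolation (bandwidth = median inter-electrode distance)
renders them on the unit-disc head model, exactly reproducing electrode
values. Rendering to images is intentionally out of scope — the numeric
tables are the tested surface.

## Numerical and degenerate-input choices

* Band bins use `lo <= f < hi`, so shared band edges are not double-counted;
  with the 256-point FFT at 200 Hz no bin falls exactly on an interior edge.
* Decimation requires an integer rate ratio; anything else errors rather
  than silently resampling.
* EDF output pads the last data record with zeros to a whole second;
  BrainVision stores float32 and round-trips annotations exactly through
  marker descriptions.
* FastICA non-convergence produces a warning and a flagged pass-through
  rather than a hard failure.
* Cross-validation cells whose preconditions fail (e.g. a missing class)
  are recorded as `NA`, never imputed.
* The global seed fans out to stage seeds through fixed offsets; identical
  configurations are bit-identical end to end.

## Problem sizes in tests and the acceptance script

The shipped analyses and checks run desk-scale versions of the full
protocol: 200 Hz generation (the pipeline's own analysis rate), 16–32 s
clips, 2-s inter-session gaps, and 1–16 subjects depending on the check,
with the full-protocol defaults (1,000 Hz, 4-min clips, 50-s gaps, 16
subjects) available by simply not overriding the generator defaults. The
16-subject evaluations behind the haptic-effect checks use DE features on
the beta and gamma bands, where the modeled effect lives.

## Known limitations

* The generator's stationary Gaussian bands cannot probe waveform-level
  artifacts (e.g. muscle spectra, electrode pops) or nonstationary
  emotional dynamics.
* Absolute accuracies depend strongly on the window-as-sample choice and
  session-grouped folding; only within-pipeline comparisons are meaningful.
* The ICA rejection criterion is a reproducible stand-in for expert
  component selection, not a replication of it.
* Delta/theta accuracies sit at chance by construction, unlike real data.
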