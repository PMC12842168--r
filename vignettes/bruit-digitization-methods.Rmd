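---
title: "Digitizing hemodialysis-access bruits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing hemodialysis-access bruits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoaccess)
```

## The clinical problem

A functioning arteriovenous fistula (AVF) or graft (AVG) produces a
continuous bruit whose character tracks the underlying hemodynamics: the
systolic phase is louder (the acoustic analogue of pulsation), the
diastolic phase quieter but clearly present in a healthy access (the
analogue of thrill). Stenosis changes this balance. A pressure gradient
at the arterial side lowers the whole pressure waveform and the bruit
softens globally; a venous-outflow stenosis raises outflow resistance
and preferentially suppresses the *diastolic* component, so the bruit
becomes more pulsatile — softer overall, but with a much higher ratio of
systolic to diastolic loudness. `phonoaccess` turns these bedside
impressions into four per-recording numbers:

* **mean peak** — mean normalized loudness at the systolic maxima,
* **mean valley** — mean normalized loudness at the diastolic minima,
* **peak-to-valley ratio** — their quotient; elevated in venous-site
  dysfunction,
* **low-frequency component (%)** — the share of spectral area in
  20–150 Hz (cardiac rhythm) versus 150–500 Hz (turbulence), over a 5-s
  segment.

## The digitization pipeline

Each mono WAV recording (integer relative loudness, −32,768..32,767;
durations of 5–30 s accepted, clinical acquisitions run 10–20 s) passes
through:

1. **Bandpass 20–500 Hz.** Bruit energy concentrates below ~500 Hz;
   below 20 Hz lives motion artifact. We use a 4th-order Butterworth
   applied forward–backward (zero phase, effectively 8 poles). The flat
   passband preserves relative loudness (±5% at band center) and zero
   phase preserves peak timing; attenuation exceeds 40 dB by 5 Hz.
2. **Rectification.** Elementwise absolute value.
3. **Contour extraction.** A centered rolling mean of 500 samples at the
   4 kHz reference rate (125 ms), with shrinking windows at the edges so
   the contour has the same length as the signal and extremum indices
   map directly to time. Implemented with cumulative sums; an
   independent per-window-mean oracle verifies it elementwise in the
   test suite.
4. **Normalization.** The contour is divided by the 99th percentile of
   the rectified signal, making every feature invariant to recording
   gain. The 90th percentile of the raw contour is kept as a QC scalar.
   (An alternative reading — normalizing the contour by its own 90th
   percentile — is possible; we chose the P99 denominator because it
   produces normalized peaks in the 0.05–0.7 range seen clinically, and
   the two percentiles then each have one role: denominator and QC.)
5. **Peak/valley detection.** Local maxima of the contour and of its
   negation (symmetric treatment), each set pruned so retained extrema
   are at least a minimum distance apart, keeping the larger amplitude
   on conflict. See the next section for how that distance is set.
6. **Outlier rejection.** Within each amplitude set separately,
   values outside `[Q1 − 0.1·IQR, Q3 + 0.1·IQR]` are discarded — a far
   stricter fence than the conventional 1.5, deliberately suppressing
   small non-physiological fluctuations; with fewer than 4 candidates
   all are retained, since quartiles of so few points are not
   meaningful. Peaks and valleys are fenced separately because the two
   populations differ by nearly an order of magnitude. All percentiles
   in the package use linear interpolation between order statistics
   (type 7), fixed for reproducibility.
7. **Band shares.** From the first detected valley, a 5-s segment of
   the *filtered* signal (so the two bands partition the analyzed
   energy exactly) is transformed with a single-taper periodogram; the
   areas under the magnitude spectrum over 20–150 and 150–500 Hz are
   integrated trapezoidally with interpolation at the exact band edges.
   If less than 5 s remains the longest tail of at least 2 s is used and
   flagged; shorter still, the value is undefined.

Undefined quantities (no valleys, zero mean valley) are reported as
missing, never as sentinel numbers, and are excluded from cohort
summaries with their counts tallied.

### The minimum peak distance, and why it adapts

The pipeline's two sample-count constants (500-sample window,
1000-sample spacing) are meaningful only relative to a sampling rate,
which the acquisition hardware does not document. We interpret them at a
4 kHz reference rate — the smallest standard rate consistent with the
device's stated 20–1000 Hz acquisition band — giving a 125 ms smoothing
window and a 250 ms spacing floor, and rescale both proportionally when
a file's rate differs so the time-domain semantics are invariant.

A fixed 250 ms spacing is not sufficient by itself. The contour of a
turbulence carrier smoothed over 125 ms retains stochastic ripple
(roughly 9% relative SD for a 20–500 Hz band), which produces several
spurious local maxima per cardiac cycle; with those in the candidate
set, the strict IQR fence centers the features on sub-cycle ripple
rather than on systole and diastole, and the extracted ratio collapses
toward 1 regardless of the truth. Lengthening the window instead
attenuates the cardiac fundamental and biases high ratios down by
30–45%. No single fixed window/spacing pair resolves this, because the
two needs pull in opposite directions.

The package therefore treats the configured spacing as a **floor** and
raises the effective spacing to 60% of the cardiac period estimated
from the contour's autocorrelation (maximum over lags of 0.3–2 s,
i.e. 30–200 bpm). This retains at most one peak and one valley per
cycle at any physiologic heart rate, while the 125 ms window keeps the
envelope attenuation small. On the seeded validation grid (envelope
ratios 2–12, 26 dB SNR, 20 recordings per cell) the extracted ratio has
a pooled median relative error around 7% and is strictly monotone in
the generated ratio. Setting `adaptive_min_distance = FALSE` in
`pipeline_config()` reproduces the literal fixed-floor rule.

### Localization by ratio profile

Upstream of a stenosis, pulsation is strong and thrill weak; downstream
the balance reverses. `site_ratio_profile()` applies this to the
site-ordered ratios (anastomosis → arterial puncture → venous
puncture): the boundary with the largest relative ratio drop points at
the stenotic segment, and profiles flat within 20% relative (the
`profile_tolerance` default) are reported as inconclusive rather than
over-read.

```{r profile}
site_ratio_profile(c(anastomosis = 10.6, arterial_puncture = 8.5,
                     venous_puncture = 5.9))
```

## The synthetic bruit generator

No patient audio can be redistributed, so validation rests on a seeded
generator whose ground truth is known:

\[
x(t) = E(t)\,c(t) + \varepsilon(t)
\]

* `E(t)` — a cardiac-cycle-periodic envelope (raised cosine by default;
  an asymmetric variant concentrates systole in a configurable fraction
  of the cycle) swinging between `valley_amp` and `peak_amp`, with
  per-cycle period jitter and a per-cycle log-normal loudness
  multiplier (`amp_jitter`) that scales peak and valley together.
* `c(t)` — a unit-RMS noise carrier synthesized in the frequency
  domain, with `low_band_fraction` of its **magnitude-spectrum area**
  in 20–150 Hz and the rest in 150–500 Hz. Defining the fraction on the
  spectral-area scale (the same scale the pipeline measures) makes the
  generator's parameter directly recoverable: for noise-free carriers
  the extracted low-frequency share lands within ~2 points of
  `100 × low_band_fraction`.
* `ε(t)` — white noise with RMS `noise_rms × peak_amp`.

The sum is scaled to 90% of full scale and quantized to 16-bit
(round half to even). Identical parameters and seed give bit-identical
recordings.

### Scenarios and calibration

`bruit_scenarios()` encodes the study conditions: normal AVF,
arterial-site and venous-site dysfunction, normal and dysfunctional
AVG, and post-angioplasty variants of the two AVF dysfunction groups.
Each scenario stores the clinical target medians (peak, valley, ratio,
low-frequency %) and draws per-recording parameters around them: the
envelope ratio log-normally with log-SD matched to the target's
interquartile range, and the low-band fraction logit-normally likewise.
Post-angioplasty scenarios generated together with their pre
counterparts share patient IDs and correlated per-patient draws, so
paired comparisons see genuine within-patient change.

Two calibration points deserve honesty:

* The normalized peak is **scale-invariant by construction** (the
  contour is divided by a percentile of the same recording), so the
  generator cannot lower a scenario's extracted peak by making the
  bruit quieter. The mechanism used instead is beat-to-beat loudness
  variability (`amp_jitter`): the P99 denominator tracks the loudest
  cycles while the mean peak averages all of them, so more variable
  beats give a lower normalized peak. This is physiologically motivated
  — unstable turbulent jets through a stenosis fluctuate more from beat
  to beat — and the per-scenario values were fixed once from a seeded
  jitter-to-peak calibration curve.
* That statistic saturates near 0.41 and ratio recovery degrades above
  `amp_jitter ≈ 0.65`, so the clinical peak medians (0.46 normal vs
  0.17–0.18 dysfunction at the arterial puncture site) are reproduced
  in **ordering and spacing**, not absolute value (simulated medians
  run ≈0.40 vs ≈0.26). All ordering-based validation is unaffected.

What the generator does *not* model: real hemodynamics (no
Navier–Stokes or Womersley flow), respiratory modulation, collateral
flow, aneurysms, device coupling, or non-stationary noise. Passing the
recovery and ordering tests therefore demonstrates that the pipeline
measures what the generator encodes — not that it is validated on
clinical audio.

## Cohort statistics

Following standard clinical-reporting practice: continuous features are
summarized as mean ± SD when a Shapiro–Wilk test at α = 0.05 accepts
normality and as median (IQR) otherwise; group comparisons use
Student's t-test (pooled variance) when both samples pass normality and
the Mann–Whitney U test otherwise (normal approximation with tie
correction, no continuity correction); paired pre/post-angioplasty
comparisons use the paired t-test or Wilcoxon signed-rank by normality
of the differences, dropping zero differences before ranking;
categorical balance uses Pearson's chi-square without continuity
correction (the uncorrected form reproduces the published sex-balance
p-values from the published counts). Multiple sites per patient are
treated as independent observations and **no multiple-testing
correction** is applied across report cells — both choices mirror the
clinical analysis this package models and are reproduction choices, not
statistical endorsements. Constant samples are summarized as
median (IQR) with zero IQR; samples below n = 3 are flagged and not
tested.

Under a log-normal null at n = 30 per group, the full
normality-then-test pipeline holds its nominal size (empirical type-I
error ≈ 0.05 over 1000 replicates, checked in the test suite).

```{r cohort, eval = FALSE}
coh <- generate_cohort(c("normal_avf", "venous_dysfunction"),
                       n_per_group = 30, seed = 1)
ft <- extract_cohort(coh)
compare_unpaired(ft$peak_valley_ratio[ft$group == "normal"],
                 ft$peak_valley_ratio[ft$group == "venous_dysfunction"],
                 feature = "peak_valley_ratio",
                 labels = c("normal", "venous_dysfunction"))
```

## Numerical choices and degenerate inputs

* Percentiles: type 7 (linear interpolation) throughout.
* Even smoothing windows center at `i + 1/2`; an affine trend is
  therefore reproduced shifted by half a sample step — irrelevant at
  the scales used but visible in exact tests.
* Tie-break in the spacing rule: candidates are visited in descending
  amplitude, leftmost first on exact ties.
* Silent recordings (P99 of the rectified signal is zero) raise a named
  error and are flagged unusable by the batch driver.
* A constant contour yields empty, flagged extremum sets, undefined
  loudness features and an undefined band share (no first valley).
* Quantization uses round half to even; the 0.9 headroom factor
  prevents clipping for any parameter combination.

## Problem sizes in the validation suite

The test suite and the acceptance script use 10-s recordings at 4 kHz;
the recovery grid runs 6 ratios × 20 recordings, the cohort-ordering
check 20 (suite) or 12 (script) seeds × 3 scenarios × 30 recordings,
and the null calibration 1000 replicates — sizes chosen so the complete
validation runs in a few minutes on a single core while leaving the
stochastic checks comfortably powered.

## Known limitations

* The adaptive spacing assumes one dominant periodicity in 30–200 bpm;
  severe arrhythmia would defeat the autocorrelation estimate (the
  fixed floor then applies).
* The extracted ratio carries a mild compression at the extremes of the
  physiologic range (~ +13% at ratio 2, −13% at ratio 12 on the
  validation grid) from ripple selection and envelope smoothing; within
  one configuration, comparisons between groups are unaffected.
* The normalized peak's dynamic range is narrower than the clinical
  one, as discussed above.
* AVG acoustics are modeled only through their scenario targets; the
  distinct mechanics of graft conduits are not simulated.
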