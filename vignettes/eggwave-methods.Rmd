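---
title: "Methods: LMMSE artifact rejection and slow-wave analysis for the EGG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LMMSE artifact rejection and slow-wave analysis for the EGG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(eggwave)
```

## The problem

The cutaneous electrogastrogram (EGG) records the gastric slow wave — a
rhythmic myoelectric oscillation near 3 cycles per minute (cpm, 0.05 Hz)
with skin-surface amplitudes of roughly 50–200 µV. In ambulatory or
long-duration recordings the signal is interrupted by motion artifacts:
bursts of a few seconds or less, on the order of millivolts, that carry
high broadband power and completely mask the slow wave in any spectral
display. Because the artifact power overlaps the 0.02–0.20 Hz analysis
band, band-pass filtering cannot remove it; deleting contaminated windows
discards large fractions of long recordings. `eggwave` instead estimates
the artifact as interference and subtracts it.

## The artifact model and the LMMSE estimator

The observed bipolar signal is modelled per sample as

$$y_t = x_t + e_t,$$

where $x_t$ is the artifact and $e_t$ the gastric signal. Over a window of
one average slow-wave cycle ($n$ samples, the sampling rate divided by the
mean peak EGG frequency), the gastric component is taken to be zero-mean
with constant variance $\sigma_e^2$:

$$\mathrm{E}[e] = 0, \qquad \mathrm{Var}(e) = \sigma_e^2 .$$

The linear minimum mean-squared error estimate of the artifact, with the
moments of $y$ estimated locally, is

$$\hat{x}_t = m_t + \frac{\max\{0,\, v_t - \sigma_e^2\}}
  {\max\{v_t,\, \sigma_e^2\}} \,(y_t - m_t),$$

where $m_t$ and $v_t$ are the mean and population variance of $y$ over the
window of $n$ samples centered on $t$, and $\sigma_e^2$ is estimated as the
mean of $v_t$ over the whole record. The two $\max$ guards handle the fact
that $\sigma_e^2$ is not known exactly: sampling variability can push a
local variance below the floor, and the guards clamp the shrinkage gain
into $[0, 1)$. The cleaned signal is simply

$$e_t = y_t - \hat{x}_t,$$

so the decomposition always reconstructs the input exactly.

The estimator has two regimes. Where the local variance sits at or below
the floor (artifact-free data), the gain is zero and $\hat{x}_t = m_t$:
cleaning reduces to subtraction of the local mean, i.e. removal of
baseline drift on the one-cycle timescale. Where a burst drives
$v_t \gg \sigma_e^2$, the gain approaches one and the burst is subtracted
almost entirely. Since quiet stretches dominate the record, the global
mean of the local variance is a robust stand-in for $\sigma_e^2$; bursts
inflate it somewhat, which only makes the filter slightly more
conservative in quiet regions.

```{r lmmse-demo}
sim <- simulate_egg(duration_s = 3600, seed = 42)
fit <- remove_artifacts(sim, value = observed)
glance(fit)
```

```{r lmmse-plot, fig.height = 5}
autoplot(fit)
```

### Numerical choices

* **Window style.** Moments use a per-sample centered sliding window;
  windows shrink at the record edges instead of padding, so no data are
  fabricated. A disjoint-block mode (`mode = "block"`) is provided for
  comparison; it produces discontinuities at block boundaries and is not
  the default.
* **Variance convention.** Population variance (divide by $n$); the
  estimator only needs one consistent convention.
* **Window length.** `default_window_n()` returns
  `round(fs / peak_freq)` forced odd (101 samples at 5 Hz and 0.05 Hz) so
  the window has an exact center sample. `peak_freq` defaults to the
  normal 3 cpm rhythm and can be overridden per recording.
* **Degenerate inputs.** If both the local variance and the floor are
  zero (a constant record), the 0/0 gain is defined as 0 with a warning:
  a constant signal holds no artifact beyond its mean.

## Spectral features

All features derive from a short-time Fourier spectrogram: consecutive
four-minute segments with 75% overlap, per-segment mean removal, a
Hamming taper, and a one-sided periodogram reported in dB
(`10 log10`, floored at −120 dB). Frequency resolution is 1/240 Hz; no
zero-padding is used. Linear bin powers are normalized so that their sum
equals the taper-corrected segment variance (Parseval), which makes band
powers comparable across tapers. Per-segment mean removal keeps DC
leakage out of the 0.02 Hz bin. Only dB *differences* enter any reported
feature, so no absolute power reference is needed.

From the spectrogram, per window:

* **band power** — mean dB power in the gastric 0.04–0.06 Hz band;
* **normalized power** — band power minus the mean dB power in the
  0.06–0.10 Hz background band, controlling for noise-floor differences
  between recordings and channels;
* **dominant frequency** — the argmax of power over 0.02–0.20 Hz;
* **percent normal** — the percentage of windows whose dominant frequency
  falls in 2–4 cpm (inclusive band edges on bin centers); below 70% is
  conventionally considered abnormal;
* **SNR** — mean dB power in 0.04–0.06 Hz minus the mean dB power at all
  other frequencies in 0.02–0.20 Hz.

Band and SNR averages are computed in the dB domain; whether such
averages should be taken on the dB or linear scale is genuinely open, so
both are implemented (`average = "db"` / `"linear"`) with dB as the
default. Note one consequence of dB-domain band averaging: a gain of
+6 dB applied to a narrowband signal raises the *band mean* by less than
6 dB when part of the band is noise-dominated, so step responses appear
compressed relative to their per-bin size.

Electrode-pair selection (`best_pair()`) scores every unordered channel
pair by the SNR of its bipolar difference and returns the argmax, with
deterministic ties toward earlier channel order. The traditional montage
(`traditional_pair()`) uses the layout: the reference electrode on the
abdominal midline halfway between the xiphoid process and umbilicus
(layout origin) and a measurement electrode 4 cm to the subject's left.
The exact grid indexing of that montage within an array is not
standardized; the nearest-position rule with a one-grid-spacing warning
is this package's interpretation.

## Manometry and the EGG–manometry correlation

The motility index summarizes antral contractility per analysis window as
the natural log of the pressure area above a 9 mmHg threshold,
$\mathrm{MI} = \ln \int (p(t) - 9)^+ \, dt$ (mmHg·s), framed with the same
four-minute/75% windows as the spectrogram so the two series align
window-for-window. The area is a Riemann sum in which each sample
represents $1/f_s$ seconds; with that convention a constant
supra-threshold pressure over a full window and a triangular peak with
zero-valued endpoints both integrate exactly to their closed forms
($\ln 240 \approx 5.48$, $\ln 300 \approx 5.70$ in the worked examples).
"Area above the threshold line" is used rather than total area under
supra-threshold excursions because it vanishes smoothly at threshold;
contraction-free windows are floored at $\ln(\varepsilon)$ with
$\varepsilon = 1$ mmHg·s (index 0) and flagged. Pressure is assumed
baseline-corrected; no intragastric baseline estimation is attempted.

The association between EGG band power (dB) and the motility index is
quantified by ordinary least-squares regression with a two-sided test of
zero slope; p-values are Bonferroni-adjusted by the number of manometry
channels examined per subject, and 0.01 is the significance level.
Paired (two related samples) and pooled-variance unpaired comparisons are
provided for condition contrasts.

## What the simulator emulates

`simulate_egg()` builds records as an exact sum of labelled components,
so every downstream stage can be scored against ground truth:

* **Slow wave**: a sinusoid at 3 cpm (configurable, including per-sample
  circadian profiles) at 100 µV — the middle of the physiological
  50–200 µV range — amplitude-modulated by a smoothed log-normal
  contraction envelope (sd 0.25 on the log scale, 600 s smoothing). The
  envelope is the physiological link to manometry:
  `simulate_coupled_manometry()` drives 3 cpm-locked pressure peaks with
  the same envelope, so the windowed motility index correlates with EGG
  band power by construction.
* **Artifact bursts**: Poisson-placed (12/h by default) raised-cosine-edged
  pulses of random polarity, 0.5–5 s long, 1–5 mV in amplitude. The
  carrier under the envelope is a 0.6 : 0.4 mix of DC offset and noise
  band-limited below 0.25 Hz, because motion has slow dynamics: this puts
  burst power on top of the 0.02–0.20 Hz analysis band, reproducing the
  full-band masking that real bursts show in spectrograms. Each burst
  also leaves an exponentially recovering baseline shift (30% of the
  burst amplitude, 120 s time constant) — the electrode-motion
  half-cell-potential disturbance familiar from skin-electrode
  recordings — bookkept in the drift component.
* **Drift**: band-limited noise below 0.01 Hz, 50 µV RMS.
* **Measurement noise**: 20 µV RMS with a 1/f spectrum, the spectral
  character of skin-electrode biopotential noise below 1 Hz. A white
  option exists, but white noise at this RMS spreads its power to the
  2.5 Hz Nyquist and leaves an unrealistically low floor in the
  0.06–0.10 Hz background band, which would let taper-leakage from the
  slow wave dominate the normalized-power background.

`simulate_ambulatory_day()` adds a meal response — each meal multiplies
slow-wave amplitude by +6 dB (power) at completion, decaying linearly in
dB over 3.5 h, so the response has returned to baseline between 3 and
4 h — and a circadian frequency profile (2.74 cpm asleep, 2.91 cpm
awake), with a time-synchronized event log. Default meal times
(08:00, 13:15, 18:30 with sleep 23:45–07:00) are chosen so that lunch and
dinner qualify as *isolated meals* (no other logged event within five
hours on either side) while breakfast, one hour after waking, does not —
isolated meals are rare in realistic logs. Meal power and circadian
frequency are controlled independently.

What the simulator does **not** emulate: biophysical dipole propagation
across the electrode array (channels share one source with fixed
attenuation plus independent noise), spatially correlated noise,
tachygastric or bradygastric dysrhythmia episodes, catheter mechanics, or
sustained artifacts such as vigorous exercise — the estimator is not
expected to recover signal during sustained artifact, and no claim about
that regime follows from passing tests. Passing the suite shows the
pipeline recovers known structure under these idealized conditions; it
does not certify performance on clinical recordings.

## Problem sizes and seeds

Validation-style experiments use 2-h records at 5 Hz (36 000 samples,
117 spectral windows); ambulatory experiments use 24-h days (1437
windows). The meal-response curve pools isolated meals across eight
simulated days, mirroring multi-day ambulatory protocols, because with
roughly two isolated meals per day the single-day curve is bound by
envelope variability (about 1 dB), not by the meal effect. Correlation
contrasts use 50 seeded replicates. All randomness flows from explicit
seeds; identical seeds give bit-identical records.

## Known limitations

* $\sigma_e^2$ is a single global constant per record. Slow changes in
  EGG amplitude (meals, circadian modulation) technically violate the
  constant-variance assumption; in practice the burst-to-signal variance
  ratio is large enough (mV vs µV) that the gain still separates the two
  regimes cleanly.
* During a burst the gastric signal is not recovered — the estimator
  subtracts nearly all of $y_t - m_t$, gastric content included. The
  value of cleaning is that burst windows stop corrupting spectral
  features, not that the slow wave inside a burst is restored.
* The local-mean subtraction acts as a high-pass at the one-cycle
  timescale: genuine sub-0.01 Hz physiology is removed along with drift.
* dB-domain band averaging compresses step responses (above); linear
  averaging is available where that matters.
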