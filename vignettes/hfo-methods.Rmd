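---
title: "Detecting high-frequency oscillations and delineating the epileptogenic zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-frequency oscillations and delineating the epileptogenic zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfotools)
```

## The problem

High-frequency oscillations (HFOs) — brief intracranial-EEG events with
at least four consecutive oscillations clearly above the background, in
the ripple (80–200 Hz) or fast-ripple (200–500 Hz) band — concentrate in
the epileptogenic zone (EZ), the tissue whose removal is necessary and
sufficient to stop seizures.  Turning HFO rates into a surgical
decision requires three ingredients, which this package implements end
to end:

1. an **automated detector** whose thresholds adapt to the channel's own
   baseline rather than to the whole segment;
2. a **false-HFO filter**: band-pass filtering turns sharp epileptiform
   transients into oscillation-shaped ringing (the Gibbs effect), and
   these artefacts must be removed before rates are interpreted;
3. a **quantitative resection criterion**: the continuous resection
   ratio of high-order HFO channels, with its 72% coverage threshold.

No patient recordings ship with the package.  A synthetic-iEEG module
generates multichannel recordings with known ground truth so that every
stage is testable, and every performance figure the package reports is
computed on those synthetic conditions.

## Detection by consecutive peaks over a modal baseline

Channels are band-pass filtered with a zero-phase (forward–backward)
windowed-sinc FIR filter.  The order is set by a 10 Hz transition width
(~661 taps at 2 kHz), giving ±5% passband gain and >40 dB stopband
attenuation per pass; zero-phase application preserves event timing,
which matters because event boundaries are defined by peak times.

The baseline is estimated from *maximum-distributed peak points*: the
mode of the rectified-peak-amplitude distribution (kernel density
maximizer) anchors the baseline, and peaks up to twice the modal
amplitude are taken as baseline peaks.  Their mean and SD set the
detection thresholds.  Because the mode is insensitive to a minority of
large events, the estimate barely moves on HFO-dense channels — the
tests verify a <10% shift in the baseline mean when bursts occupy 5% of
the record.  Two cutoffs play different roles:

* `mode_cutoff = 2` — which peaks contribute to the amplitude
  statistics;
* `segment_cutoff = 4` — which peaks *interrupt* a baseline segment.
  In band-limited noise roughly one peak in eight exceeds twice the
  mode by chance, so demanding 200 ms of exclusively sub-2×-mode peaks
  would leave no segments at all; four times the mode is practically
  never exceeded by noise, so segments are runs free of genuine
  high-frequency activity, as intended.

Baseline segments (≥200 ms) provide the per-frequency mean Morlet power
used by the false-HFO constraint below.

An event requires `n_low` consecutive rectified peaks above
`mean + k_low·SD` containing at least `n_high` consecutive peaks above
`mean + k_high·SD`.  Defaults are the SEEG-optimized values: ripples
8 peaks > 3 SD with 6 > 10 SD; fast ripples 8 > 3 SD with 6 > 9.5 SD
(two rectified peaks per cycle, so 8 peaks ≈ the visual
four-oscillation rule).  Events closer than 10 ms are merged.
`optimize_parameters()` re-derives such parameter sets on gold-standard
marks by exhaustive traversal of the Youden index
(sensitivity + specificity − 1), constrained to specificity ≥
sensitivity.

## False-HFO identification

A genuine HFO is an island in the time–frequency plane: power in its
band rises above the neighbouring lower frequencies.  A filtered
transient is a mountain: power decreases monotonically with frequency.
The classifier computes a Morlet spectrum (analytic mother wavelet,
ω₀ = 6 cycles, L2-normalized so stationary noise is frequency-flat;
scales use the standard Fourier-factor correction so tone peaks land on
the tone) of the *raw* signal in a 1 s window around the event, takes
the event's PSD, and accumulates

S = Σ_{f, Δf} max(0, Power(f) − Power(f − Δf))

over the event's band, with Δf from 1–200 Hz (ripples) or 200–600 Hz
(fast ripples) in 1 Hz steps, zeroing any difference below the
channel's baseline mean power at f.  S = 0 means no energy increase
anywhere in the band: the event is declared false.

Two numerical choices matter:

* **PSD over the event period, not a single column.**  The single
  midpoint column is sensitive to interference between a transient's
  slow and fast components, which can carve a small dip-then-recovery
  into the spectrum and let an artefact through; averaging over the
  event period removes this fragility (on the synthetic conditions it
  moves transient rejection from 88% to 100% without costing a single
  genuine burst).  The midpoint variant remains available
  (`method = "midpoint"`).
* **`f_floor = 5` Hz.**  A 6-cycle wavelet below ~5 Hz is longer than
  the 1 s analysis window, so power there is not estimable; comparisons
  against those bins are skipped.

## The resection ratio and the 72% rule

After false events are removed, channels with more than 1 true event
per minute are ranked by rate in descending order.  The *continuous
resection ratio of high-order HFO channels* is

ratio = #ChannelConRem / #Channel,

the number of channels continuously resected from the top of the
ranking (up to the first spared channel) over the number of ranked
channels.  Rate ties are broken lexicographically by label for
determinism; a "pessimistic" mode puts spared channels first within a
tie to lower-bound the ratio.  Group statistics (median, quartile IQR,
bootstrap-percentile 95% CI of the median with 10,000 resamples, exact
Mann–Whitney p) compare Engel class I (good) against class ≥ II (poor)
patients; the lower CI bound of the good group is the candidate
coverage threshold, and `delineate_ez()` applies the published 72%
value: a resection covers the EZ when the ratio reaches the threshold,
and the EZ itself is the top ⌈0.72 · n⌉ channels.  The Mann–Whitney p
is computed by exhaustive permutation enumeration for combined sizes up
to 16 — ratio data are tie-heavy at 0 and 1, where the classical exact
distribution does not apply — and by the tie-corrected normal
approximation beyond that.

## What the synthetic data emulate

`synth_spec()`/`gen_recording()` produce multichannel 1/f^α Gaussian
background (α = 1, broadband SD 30 µV — typical interictal iEEG scale)
with three insertable signal classes:

* **Bursts** (genuine HFOs): Tukey-windowed (25% taper) sinusoids.  A
  Hann envelope would attenuate the edge cycles so strongly that even a
  large six-cycle burst could not produce six consecutive supra-10-SD
  peaks; the Tukey plateau keeps the written amplitude meaningful.
  Amplitudes are expressed in band baseline SDs — the SD of the
  band-filtered background — so generator knobs map onto detector
  thresholds; defaults are 8 cycles at 12 SD.
* **Transients** (false-HFO generators): a sharp exponential cusp
  (decay width/2 ms) plus a biphasic Gaussian-derivative fast component
  at 0.6 of the apex amplitude (σ = width/6 ms), default width 20 ms,
  apex 800 µV.  The cusp supplies the strong, monotonically decaying
  low-frequency power of a real interictal discharge; the fast
  component makes the transient ring above threshold in the ripple
  band.  A pure Gaussian derivative would not do: its spectrum *rises*
  up to a band-limited bump, which is spectrally a genuine oscillation,
  not a filtering artefact.  With a 20 ms width the ringing is almost
  entirely confined to the ripple band, reproducing the observation
  that ripples are far more susceptible to the Gibbs effect than fast
  ripples.
* **Cohorts**: per-patient channel-rate tables with resection flags
  arranged to hit designed ratios — near 1 for good-outcome patients,
  near 0.1 for poor-outcome — mirroring the published fast-ripple
  medians (good 1, poor 0.09).

The standard validation conditions (`validation_specs()`) are 100
bursts at 12 SD across two ripple and two fast-ripple channels plus one
insertion-free channel, and 100 transients, in 90 s recordings at
2 kHz; the test suite and the acceptance script measure detection
sensitivity, the false-positive count on the quiet channel, transient
rejection and burst retention rates, and the cohort statistics on a
10 + 10 patient design.  These are deliberately idealized: the
background is stationary and Gaussian, bursts are windowed tones, and
transients are a single stereotyped morphology.  Passing them shows the
algorithms implement their definitions and separate the two designed
signal classes at comfortable SNR; it does not certify performance on
clinical recordings, where non-stationarity, artefacts, physiological
HFOs and electrode differences dominate the error budget.

## Degenerate inputs and edge policies

* Epoch selection: an epoch qualifies when its delta (0.5–4 Hz) power
  fraction exceeds 25% of its own 0.5–fs/2 power (per-epoch reading of
  the slow-wave rule; a cross-epoch upper-quartile mode is available).
  No qualifying epoch is a warning, not an error.
* Baselines need ≥10 s of signal and ≥50 peaks; if no 200 ms quiet run
  exists the estimator falls back to the lowest-decile peaks with a
  warning.
* Recordings below 1 kHz sampling are rejected (fast-ripple band
  unanalyzable); times are 0-based seconds over half-open intervals.
* Matching is greedy one-to-one by largest temporal overlap; any
  positive overlap counts.
* Undefined quantities (no visual marks, empty rankings, one-patient
  groups) are NaN/NA with warnings, never silent zeros.

## Reproducing the numbers

Every random stage (background, insertion jitter, cohort design,
bootstrap) is seeded explicitly; identical seeds give bit-identical
recordings and byte-identical pipeline tables.  `scripts/acceptance.R`
regenerates the validation conditions from a command-line seed and
recomputes all reported quantities from scratch; the problem sizes
above (90 s recordings, 100 events per class, 20 patients, 10,000
bootstrap resamples) are the package's standard validation scale.
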