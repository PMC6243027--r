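# hfotools

Automated detection of high-frequency oscillations (HFOs) in
intracranial EEG, removal of filtering-induced false HFOs, and
epileptogenic-zone delineation from the continuous resection ratio of
high-order HFO channels.

## Who this is for

HFOs — brief iEEG events with at least four consecutive oscillations
clearly above baseline, split into ripples (80–200 Hz) and fast ripples
(200–500 Hz) — are a leading interictal biomarker of the epileptogenic
zone (EZ). This package is for epilepsy researchers and detector
developers who need the full chain from raw multichannel recordings to
a surgical-coverage statistic, plus a synthetic-iEEG generator with
ground truth so the chain can be validated without patient data.

## The method

**Detection.** Channels are band-pass filtered with a zero-phase FIR
filter. The baseline is estimated from *maximum-distributed peak
points*: the modal rectified-peak amplitude anchors the estimate, so
HFO-dense channels do not inflate their own thresholds. An event
requires `n_low` consecutive rectified peaks above
`mean + k_low · SD` containing `n_high` consecutive peaks above
`mean + k_high · SD`; the SEEG-optimized defaults are 8 > 3 SD with
6 > 10 SD (ripples) and 8 > 3 SD with 6 > 9.5 SD (fast ripples).
`optimize_parameters()` re-derives such sets on marked data by
traversal of the Youden index (sensitivity + specificity − 1).

**False-HFO removal.** Sharp transients pass a band-pass filter as
oscillation-shaped ringing (Gibbs effect). For each detected event the
classifier takes the Morlet-spectrum PSD of the *raw* signal over the
event and accumulates the frequency-offset power difference

    S = Σ_{f, Δf} max(0, Power(f) − Power(f − Δf))

over the event's band (Δf = 1–200 Hz for ripples, 200–600 Hz for fast
ripples, 1 Hz steps), zeroing differences below the channel's baseline
mean power. Genuine HFOs are spectral islands (S > 0); filtered
transients inherit the spike's monotonically decreasing spectrum
(S = 0) and are discarded.

**EZ delineation.** True-event rates above 1/min rank the channels in
descending order; the *continuous resection ratio* is the number of
channels continuously resected from the top of the ranking over the
number of ranked channels. Good-outcome (Engel I) and poor-outcome
(Engel ≥ II) groups are compared with an exact Mann–Whitney test, and a
resection is judged to cover the EZ when the ratio reaches the 72%
threshold.

## Worked example

Simulate one channel carrying three genuine 12-SD ripple bursts and one
channel carrying two sharp transients, then detect, classify and rank:

```r
library(hfotools)

spec <- synth_spec(
  n_channels = 2, dur = 60, bg_sd = 30,
  bursts = data.frame(channel = "ch1", time = c(10, 25, 40), freq = 120,
                      n_cycles = 8, amp_sd = 12),
  spikes = data.frame(channel = "ch2", time = c(18, 33), width_ms = 20,
                      amp_uv = 800),
  seed = 42)
sim <- gen_recording(spec)

det <- detect_recording(sim$rec, "ripple")
cls <- remove_false(det$events, sim$rec, det$baselines)
print(cls)
#> <hfo_classification> 5 events: 3 true, 2 false
#>   ripple: 40.00% false
events_table(cls$events)[, c("channel", "start", "end", "n_peaks", "verdict")]
#>   channel  start     end n_peaks   verdict
#> 1     ch1 10.003 10.0605      15  true_hfo
#> 2     ch1 25.003 25.0600      15  true_hfo
#> 3     ch1 40.003 40.0635      16  true_hfo
#> 4     ch2 17.963 18.0545      17 false_hfo
#> 5     ch2 32.946 33.0495      19 false_hfo
```

All five suprathreshold events are found; the three seeded bursts are
kept as true HFOs and both transient artefacts are rejected. Checking
against the ground truth and ranking the channels:

```r
evaluate_detection(match_events(cls$true_events, sim$truth$events))
#> <hfo_evaluation> tp=3 fp=0 fn=0 | sens 100.00%  spec 100.00%  Youden 1.0000

rates <- channel_rates(cls$true_events, duration_min = 1,
                       data.frame(channel = c("ch1", "ch2"),
                                  removed = c(TRUE, FALSE)))
rank_channels(rates)
#> <hfo_ranking> 1 channel(s) > 1/min; 1 continuously removed; ratio 1.00
```

Only `ch1` exceeds 1 true event/min; it was resected, so the continuous
resection ratio is 1.0 — `delineate_ez()` would report the resection as
covering the EZ at the 0.72 threshold.

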