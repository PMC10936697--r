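---
title: "REG pulse-wave morphology and the REGx autoregulation index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{REG pulse-wave morphology and the REGx autoregulation index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regwave)
```

# The measurement problem

Rheoencephalography (REG) measures the electrical impedance of the head; its
pulsatile component tracks beat-by-beat cerebral blood volume change. Two
clinically meaningful readings can be extracted from such recordings without
any invasive probe:

* **Pulse-wave morphology.** The intracranial pulse carries three sub-waves —
  P1 (percussion, arterial inflow), P2 (tidal, reflecting intracranial
  compliance) and P3 (dicrotic, venous/valve). With normal compliance P1
  dominates (`P1 > P2`, "good ICC"); as compliance falls the tidal wave grows
  (`P2 > P1`, "poor ICC") until the three waves fuse into a single triangular
  hump. The *anacrotic time* (onset-to-P1 rise time) separately indexes
  arterial elasticity; values at or above 180 ms are the arteriosclerotic
  pattern.
* **Autoregulation state (REGx).** The pressure-reactivity index PRx is the
  moving Pearson correlation of 10-second averages of arterial pressure and
  intracranial pressure over a 5-minute window: positive correlation means
  pressure is transmitted passively (impaired autoregulation), negative
  correlation means active vasomotor counter-regulation. REGx computes the
  identical statistic non-invasively, pairing a head REG channel with a
  peripheral (arm) bioimpedance channel.

`regwave` implements both readings as a tested pipeline, together with the
challenge analytics used to probe them (30-second breath-holding as a CO2
reactivity test; head-down tilt as a volume-loading test) and a synthetic
signal generator that renders complete sessions with known ground truth.

# Pipeline stages and their numerical choices

## Mains suppression

Powerline interference is removed by a centred running average of
`window_s = 0.04` s. At 200 Hz this window spans 8 samples — exactly two
cycles of a 50 Hz component — so the mains fundamental is a true zero of the
filter, not merely attenuated: the tests require at least nine orders of
magnitude of suppression on a pure 50 Hz tone. The pulse wave itself (most
energy below ~15 Hz) passes with only a few percent amplitude loss. Edges use
a shrinking window so output length equals input length, and the centred
(zero-phase) form keeps latencies comparable across channels. For even window
lengths the window covers one more sample after the centre than before; this
half-sample asymmetry is irrelevant at the latency tolerances used here.

## Artifact masking

Blink and talking artifacts are flagged by robust z-scores (median/MAD) of
the sample values and of their first differences, on any channel; flagged
runs are dilated by `pad_s = 0.5` s and merged. The thresholds (amplitude
z = 8, derivative z = 20) must sit above normal beat dynamics — the systolic
upstroke of a clean synthetic session reaches a derivative z of roughly 14 —
while staying below artifact excursions, and were calibrated once against the
seeded simulator: the clean session yields an empty mask while injected
blinks and talk bursts are detected with at least 95% sensitivity. Masked
stretches are excluded from every downstream statistic, never interpolated.
Analysis epochs are taken from the clean complement as maximal stretches
chopped to 10 s, discarding fragments under 5 s — the conventional 5–10-s
artifact-free reading periods.

## Beat segmentation

Beats are delimited by pulse-wave minima, matching the cursor-to-minimum
convention of manual reading. Candidates are local minima with prominence at
least 30% of the channel's 5th-to-95th percentile amplitude; a refractory
period of `60 / hr_max` seconds suppresses intra-beat notches (deepest minima
win, deterministically); onset candidates stranded far above their
neighbours' diastolic floor (over 5 MAD or 5% of the amplitude range after
running-median detrending) are rejected; and onset pairs implying a heart
rate outside 40–180 bpm are dropped. Plateau extrema resolve to their first
sample, a deterministic tie-break. A flat channel yields zero beats, not an
error.

## Per-beat morphology

Within a beat, amplitudes are measured relative to the onset (minimum) value.
P1 is the first local maximum; the descending limb after P1 is then examined
for a *shoulder* — a deceleration/re-acceleration of the decay in which the
derivative never turns positive, detected as an interior local maximum of the
smoothed first difference that stays negative. If a shoulder precedes the
next distinct maximum, the shoulder is taken as P2 (its amplitude read at the
derivative-defined location, keeping tidal statistics computable) and the
next maximum as P3; otherwise the next maximum is P2 and the one after it P3.
A beat with a single maximum and no shoulder is *fused*: class `TRIANGULAR`.
Classification is `GOOD_ICC` when `P1 > P2`, `POOR_ICC` when `P2 >= P1` (the
tie breaks toward pathology), and a beat with no detectable P1 is flagged
rather than classified. The anacrotic boundary at exactly 180 ms is classed
`PROLONGED` (the threshold is a floor for the pathological class).

## Epoch averaging and the moving correlation

Each channel is reduced to one scalar per consecutive 10-s epoch. The default
epoch feature is the mean of the smoothed signal; a per-epoch pulse-amplitude
feature (95th minus 5th percentile) is provided as an alternative because the
literature does not pin down which scalar the original software correlated —
the mean is the default here. Epochs with fewer than half their samples
unmasked are invalid.

The index is the Pearson correlation over the valid epoch pairs whose centres
fall in `(t - 300, t]`, emitted from `t = 300` s onward and stepped by
`update_s` (10–60 s): a full window holds 30 pairs. Three policies matter:

* **No early emission.** Nothing is emitted before one full window exists;
  the first value appears at exactly 300 s.
* **Zero variance.** Pearson correlation is undefined for a constant series;
  such windows are emitted as invalid (`NA`, flagged), never forced to ±1.
  This is why the sine-pair demonstration includes a small common slow drift:
  two identical fast sinusoids have epoch means of zero and would otherwise
  produce no index at all, whereas any common drift gives identical epoch
  means (correlation +1) in phase-aligned segments and sign-flipped means
  (−1) in inverted segments.
* **Depleted windows.** Windows with fewer than `min_pairs = 20` of the 30
  possible pairs (artifact-depleted) are invalid; the threshold is an
  engineering default, set well above the two-pair minimum at which the
  statistic becomes meaningless.

Values below zero are classed `ACTIVE` (intact autoregulation), values at or
above zero `PASSIVE` — the tie at zero conservatively toward impairment. Two
derivations of the index (bifrontal- and bitemporal-based) are compared by
the squared Pearson correlation of their time-aligned valid values.

## Breath-hold analysis

The baseline is the mean P1 over clean beats in the 30 s before the hold
command. The response maximum is read over periods, not single beats: each
beat's P1 is replaced by the mean over the beats of the surrounding 5-s
window before the maximum is located. This mirrors how amplitudes are read
from 5–10-s periods in practice and removes the upward bias of a
single-beat argmax under beat-to-beat amplitude variability. The search runs
from the command to 90 s after it — responses peak during the hold, shortly
after its end, or up to a minute later, so the window must cover all three;
90 s is a configurable engineering default. The peak delay is the time from
the command to the beat carrying the period maximum, and the response size is
the baseline-percent change `BL% = 100 (max − baseline) / baseline`.

## Control vs head-down tilt

Condition means of P1 and P2 (shoulder-derived P2 included) and their BL%
changes are computed per channel, with a paired t test on per-epoch (10-s)
mean amplitudes — per-beat values are serially correlated, so beats are a
misleading unit of analysis; epoch means are closer to exchangeable. Control
epoch *i* is paired with tilt epoch *i* and surplus epochs are dropped. The
unit of analysis in the original studies is not stated; this package
documents its own choice rather than claiming fidelity. Degenerate paired
tests follow a stated convention: identical vectors give `t = 0, p = 1`;
zero-variance non-zero differences give an unbounded, flagged statistic with
`p = 0`. Beats inside breath-hold response windows are excluded from the
condition means so the CO2 response does not contaminate the posture
comparison.

# The synthetic generator

Real REG recordings of this kind are not publicly deposited, so every stage
is validated against a seeded simulator whose ground truth is known by
construction. A scenario specifies posture segments, per-posture beat
templates, breath-hold events, mains, drift, artifact rate and seed; the same
scenario and seed render bit-identical signals.

* **Beats** are sums of three Gaussian sub-waves (latency, amplitude, width
  each), a deliberately simple shape whose peaks, fusion behaviour and
  amplitude ratios are fully controllable, plus a linear *diastolic runoff*
  (5% of beat amplitude) so the train descends into each onset the way a
  real pulse wave does — without it the inter-beat baseline is flat and
  onset minima are not localisable against noise.
* **Breath-hold responses** multiply beat amplitudes by a gain that ramps
  linearly from `response latency` after the command to a configurable peak
  (default 10 s after the hold ends) and recovers linearly over 30 s. The
  ramp-and-turnover shape keeps the configured peak time identifiable; a
  profile with a flat top would make "peak delay" unrecoverable from noisy
  beats and the ground truth would not suffice to score the analysis.
* **Amplitude variability** is respiration-structured: a 2% sinusoidal
  modulation at 0.25 Hz common to all channels plus 0.5% white per-beat
  jitter. Real beat-to-beat variability is respiration-dominated, which is
  what makes 5–10-s period reading effective; a purely white model of the
  same magnitude would be both unphysiological and unreadable.
* **Slow drift** (amplitude 0.05, period 150 s) is added to head and arm
  channels either in phase or inverted per posture segment — this is the
  REGx ground truth (+1 or −1). The default session uses in-phase drift
  during supine control and inverted drift during tilt, so the index should
  swing from passive to active at the posture change.
* **The default session** is 30 min: 15 min supine control with three 30-s
  breath-holds (gain 1.16), then 15 min head-down tilt in which the tidal
  amplitude is raised by a factor 1.4 over a supine P2/P1 of 0.8 — tilt
  beats are therefore `P2 > P1` (poor-compliance morphology) with a P2
  elevation of +40 BL%. Mains at 50 Hz, one artifact per minute. These
  defaults are free modelling parameters, not claims about human responses.

What the simulator does **not** emulate: CO2 kinetics and real
cerebrovascular dynamics (the breath-hold gain is imposed, not produced by a
physiological model), electrode/skin physics, heart-rate variability,
non-stationary artifact morphologies, or coupling between posture and heart
rate. Passing tests therefore demonstrate that the *analysis* recovers the
structure the *model* generates — parameter recovery, not clinical validity
on human recordings.

# Storage formats

The native dialect stores samples as little-endian 32-bit floats
(channel-interleaved) behind a magic string and a fixed header, with an ASCII
metafile carrying setup keys and one tab-separated line per annotation.
Round-tripping is byte-stable: a written file reads back to exactly the
float32 values stored, and re-writing those reproduces the file bit for bit
(double-precision inputs are cast to float32 once, on first write). The EDF
export uses the standard's 16-bit scaling with per-channel physical bounds
chosen from the data range — the bounds are themselves parsed back from their
8-character ASCII fields so writer and reader share an identical scale, and a
round trip is accurate to one quantization step. Constant channels are padded
to a 2-unit scale to avoid a degenerate mapping. CSV export writes a time
column plus one column per channel with annotations in a tab-separated
sidecar. The reader rejects malformed native input loudly: a wrong magic
string or version is a format error and a truncated payload reports expected
versus found sample counts.

# Problem sizes and runtime

The test suite exercises full 30-minute, three-channel sessions at 200 Hz
(~360 000 samples per channel) for end-to-end recovery, shorter 7–14-minute
sessions for unit-level checks, and the 25-minute sine-pair demonstration for
the index; these sizes were chosen so the complete suite runs in about a
minute while still covering hundreds of beats per condition and dozens of
correlation windows.

# Known limitations

* No calibration to mmHg: morphology classes and BL% changes are relative
  statements; the pipeline deliberately does not estimate intracranial
  pressure values.
* The human-subject group statistics of REG studies are not reproducible
  here because the underlying recordings are not deposited; the simulator
  stands in for them with known-truth surrogates.
* Artifact detection is threshold-based and tuned on the simulator; heavily
  contaminated real recordings may need channel-specific thresholds.
* The breath-hold response latency is a generator parameter but is not
  estimated by the analysis (no onset-reading operation is defined); timing
  recovery is assessed through the peak delay.
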