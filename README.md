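# regwave

Analysis of rheoencephalography (REG) and peripheral bioimpedance
recordings: pulse-wave morphology, the REGx cerebral-autoregulation index,
and breath-hold / head-down-tilt challenge analytics.

## The problem

REG measures the electrical impedance of the head at a few hundred hertz
sampling; its pulsatile component tracks cerebral blood volume changes beat
by beat. Two clinically meaningful, fully non-invasive readings can be
derived from it, and this package implements both as a reproducible
pipeline for physiologists and neuromonitoring researchers:

**Pulse-wave morphology.** The intracranial pulse carries three sub-waves:
P1 (percussion), P2 (tidal) and P3 (dicrotic). Their relative amplitudes
index intracranial compliance (ICC):

| pattern | class | meaning |
|---|---|---|
| P1 > P2 | `GOOD_ICC` | normal volume buffering |
| P2 ≥ P1 | `POOR_ICC` | compromised compliance |
| waves fused into one hump | `TRIANGULAR` | further worsening |

The anacrotic time (pulse minimum to P1 maximum) separately indexes
arterial elasticity, with 180 ms as the threshold for the prolonged
(arteriosclerotic) pattern, and amplitude changes across conditions are
expressed as percent of baseline, `BL% = 100 (x − x_ctrl) / x_ctrl`.

**Autoregulation (REGx).** The pressure-reactivity index PRx is the moving
Pearson correlation

    REGx(t) = cor( {head_i}, {arm_i} : epoch i in (t − 300 s, t] )

of 10-second epoch averages of two channels over a 5-minute window (30
pairs), renewed every 10–60 s. Positive values mean passive transmission
(impaired cerebral autoregulation); negative values mean active
counter-regulation (intact autoregulation). REGx is the same statistic
computed from a head REG channel and an arm bioimpedance channel, replacing
the invasive pressure probes.

Because recordings of this kind are not publicly deposited, the package
includes a first-class synthetic-signal generator (`scenario()`,
`generate_session()`, `generate_sine_pair()`) that renders complete
annotated sessions — P1/P2/P3 beat templates, breath-hold gain responses,
posture-dependent morphology, mains contamination, drift with controllable
head/arm phase, blink/talk artifacts — with per-beat ground truth, so every
stage of the analysis is testable end to end.

## Worked example

Render the default 30-minute challenge session (15 min supine control with
three 30-s breath-holds, then 15 min head-down tilt with an elevated tidal
wave) and run the full pipeline:

```r
library(regwave)
ses <- generate_session(default_session_scenario(seed = 42))
res <- analyze_session(ses$record)
print(res$report)
```

```
Session report
==============
 subject    channel p1_control p1_hdt p1_bl_percent p2_control p2_hdt
 session  bifrontal     0.9709 0.9713       0.03169     0.8008 1.1068
 session bitemporal     0.8741 0.8745       0.04713     0.7209 0.9966
 p2_bl_percent p2_p_value n_control n_hdt regx_r2
         38.21 3.737e-111       686  1011       1
         38.24 2.516e-114       686  1011       1

Breath-holds
 subject bh_start_s baseline_p1 max_p1 peak_delay_s bl_percent
 session        120      0.9694  1.116        39.40      15.08
 session        300      0.9706  1.115        40.24      14.86
 session        480      0.9699  1.116        39.40      15.04
```

Reading the numbers: P1 is unchanged by the tilt (BL% ≈ 0) while P2 rises
by ≈ 38% of baseline — recovering the generative tilt P2 gain of 1.4 within
the smoothing bias — so control beats classify `GOOD_ICC` and tilt beats
`POOR_ICC`. Each breath-hold produces a ≈ 15% pulse-amplitude increase
(generative gain 1.16) peaking ≈ 40 s after the command (generative truth
40 s: the 30-s hold plus a 10-s post-hold peak). `regx_r2 = 1` says the
bifrontal- and bitemporal-derived indices track each other across the
recording. The index itself:

```r
rx <- res$regx$bifrontal
median(rx$values[rx$valid & rx$times <= 870])   #  0.98  (passive: in-phase drift)
median(rx$values[rx$valid & rx$times > 1260])   # -0.96  (active: inverted drift)
```

matching the session's ground truth of +1 during control and −1 during
tilt.

A command-line interface wrapping the same functions is installed at
`inst/cli/regwave` with subcommands `simulate`, `convert`, `preprocess`,
`pulses`, `regx`, `challenges` and `report`.

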