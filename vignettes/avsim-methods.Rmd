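---
title: "avsim: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{avsim: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsim)
```

`avsim` simulates accelerometer-based atrial mechanical sensing in a
leadless pacemaker: wavelet signal synthesis, a Monte Carlo virtual-patient
layer, the device timing-cycle state machine, two generations of automatic
A3-threshold adaptation, the three-phase Atrial Sensing Setup, and
atrioventricular-synchrony (AVS) scoring with paired statistics. This
vignette records the model, its tunable parameters, and the design choices
made where the behavior of the real device is not public.

## 1. Signal model

Each accelerometer deflection (A1–A4) is a Ricker wavelet
$w(t) = (1 - 2\pi^2 f^2 t^2)\,e^{-\pi^2 f^2 t^2}$ with peak frequency
$f = 20$ Hz, scaled by a per-beat amplitude in m/s². A cycle's trace is the
rectified (absolute-value) sum of its components sampled at 1 kHz. No
band-pass filter is applied: the wavelet is already band-limited and the
device display the model imitates shows a rectified waveform.

**Support and onset.** The wavelet is truncated at $|t| \le 2.5/f$
(125 ms at 20 Hz), where its amplitude is below $10^{-5}$. Because the
Gaussian envelope decays extremely fast, the *perceptible* extent is much
narrower: the amplitude falls to ~2 % of the peak $0.8/f$ (40 ms) from it.
Components specified by a nominal start or end time therefore place their
peak one onset width (40 ms) inside that time: A2 peaks 40 ms after its
start delay, A3 peaks 40 ms before the scripted A3 Signal End, A4 peaks
40 ms after P-onset + A4 delay. This makes "the A3 ends at $T$" observable:
a threshold detector recovers $T$ to a few tens of ms, which is what the
setup algorithm and the parameter-recovery tolerance (±50 ms) require. Had
the peak been placed at the mathematical support edge (125 ms in), no
threshold measurement could locate the scripted end.

**Timing defaults** (all configurable in `beat_timing()`): A1 peak fixed at
50 ms after the ventricular event with amplitude 3.0 m/s²; A2 starts at the
A2 delay (default 300 ms) with amplitude 2.0 m/s² — both sit inside the
550 ms PVAB, so their fixed values cannot affect detection; A4 starts
90 ms after P-wave onset; the A3 Signal End carries optional Gaussian
jitter of SD 0, 17 or 33 ms (the two positive values correspond to the
"50 ms" and "100 ms" variation options of the hardware bench this design
follows).

**A7 summation** is binary: whenever the A4's nominal start precedes the
(jittered) A3 Signal End the two wavelets superimpose sample-wise and the
ground truth flags `a7 = TRUE`. The real degree of summation varies with
physiology; only the binary rule is modeled, which likely flatters
detection of borderline A7s.

**Rate adjustment of the A3 end** (`auto_adjust_a3_end`, default off)
scales the A3 Signal End by RR/1000 for cycles shorter than 1000 ms with a
floor of A2 delay + 100 ms. The option exists on the hardware bench but its
law is not public; the linear law is a stand-in and is off by default —
note that with it on, the A3 would retreat as fast as the advancing A4 and
A7 would rarely form.

**Baseline noise** is not modeled (the bench runs it disabled). A
consequence worth knowing: with a noise-free trace, threshold-crossing
times on a wavelet edge vary by only a few ms per m/s² of threshold, so
threshold-dependent effects are carried by amplitude selection across
cycles rather than by within-cycle decay, which real oscillatory A3 decay
would amplify.

## 2. Virtual patients

A `patient_script()` holds, per accelerometer vector combination (1+2,
1+3, 2+3, 1+2+3), truncated-normal A3 and A4 amplitude distributions
(rejection-sampled; `sd = 0` degenerates to the mean; a `gain` knob stands
in for the gain-matching loop a bench with real recordings would run), an
hourly mean sinus-interval profile, a ±5 % uniform beat-to-beat interval
modulation (uniform chosen as the maximum-entropy bounded option), per-beat
PAC/PVC probabilities, and the timing model. All per-beat draws are
independent — deliberately, as electromechanical coupling is out of scope.

PAC prematurity is 70 % of the scheduled interval (resetting the sinus
clock), a PVC is a ventricular ectopic at 80 % of the interval with no
P-wave or A4 and a compensatory pause. These fractions are modeling
choices; ectopy burden is intended for ambulatory sessions.

**Synthetic cohort.** `make_synthetic_cohort()` cycles three archetypes
(weighted 1:2:1) chosen to reproduce the documented failure modes rather
than any real patient:

| archetype | A3 mean (m/s²) | A4 mean (m/s²) | A3 end (ms) | high-rate block |
|---|---|---|---|---|
| well_separated | 1.4–1.8 | 4.2–5.0 | 720–780 | 75–81 bpm |
| a7_undersenser | 1.6–2.0 | 4.2–5.0 | 730–790 | 87–92 bpm |
| a3_oversenser | 2.2–2.6 | 4.2–5.0 | 840–880 | 83–88 bpm |

A4 means sit where half-the-median A4 thresholds land near 2.0–2.4 m/s²
and isolated-A3 95th percentiles near 2.2–3.0 m/s², the plausible clinical
ballpark for this device family. One two-vector combination (randomized)
carries the full A4; the others are attenuated projections (×0.5–0.8) and
1+2+3 sits at ×0.9, so vector selection is non-trivial but solvable. Each
hourly profile is two rest entries then two high-rate entries; sessions
compress "hours" via `hour_length_min` so a 60-min run exercises a rest
block and a sustained >80 bpm episode.

What a green cohort test establishes — and what it does not: the
*mechanisms* (A7 formation at high rate, adaptive-threshold ratchet,
isolated-A3 learning, window-end contamination) behave directionally as
described; absolute AVS percentages depend on these synthetic
distributions and must not be read as clinical predictions.

## 3. Device state machine

Cycle origin is the ventricular event. No sensing in `[0, pvab)`
(550 ms nominal); first rectified sample ≥ A3 Threshold in
`[pvab, windowEnd)` raises AM, else first sample ≥ A4 Threshold in
`[windowEnd, next V)`; one AM per cycle (no re-arming — an open question
about the real device, resolved conservatively); VE marks the window end.
In VDD the AM is tracked with a pace at AM + 20 ms — the AM→VP interval is
not public, so a short fixed delay is used and exposed — delayed to the
upper-tracking-rate boundary when needed (no mode switching; tracking
beyond the UTR is not modeled). Without an AM the lower-rate timeout
paces. In VDI, AMs are recorded but never tracked. The A3 Window End is
rate-adaptive between its programmed Min and Max: Max at cycle lengths
≥ 1000 ms, Min at ≤ 667 ms, linear in between snapped to the 25 ms
programming grid (the grid is inferred from the published programmed
values, all multiples of 25).

Two engines implement identical semantics: `engine = "dense"` synthesizes
and scans a full 1 kHz trace per cycle; `engine = "event"` evaluates the
analytic wavelet sum only on grid points where component supports
intersect the sensing windows. Their agreement (exact in practice, ≤ 1
sample period by contract) is a standing regression test; the event engine
runs long cohort sessions at desk scale.

## 4. Threshold algorithms

**Auto (first generation, emulated).** The real update law is unpublished.
The emulation appends each cycle's A3-window maximum to an 8-cycle buffer;
every 8 cycles the threshold becomes `max(buffer) + 0.5`, clamped to
`[a4_threshold + 0.5, 6.0]`. This is the simplest rule that reproduces the
documented drift: during sustained >80 bpm episodes the window holds the
summated A7, so the threshold ratchets to just above the recent A7 maximum
and subsequent, slightly smaller A7s go undetected. Every constant is
config-exposed; this module is behavioral emulation, not re-implementation.

**Auto+ (second generation).** Cycles carrying an isolated A3 — not
ectopic, and either the AM fell more than 40 ms after the window end (A4
clearly outside) or the instantaneous atrial rate was below 80 bpm — feed
a histogram of A3-window maxima (bins 0–10 m/s², width 0.1; the bin width
and range resolve the worked example 2.1 → 3.1 m/s² exactly). Once per
day the nearest-rank 95th percentile plus the programmable margin (nominal
1.0 m/s²) becomes the new threshold and the histogram resets (reset, not
decay, is assumed). The 40 ms / 80 bpm guard values are design choices.
`day_length_min` is configurable so desk-scale tests exercise the daily
update; the daily cadence — not the percentile — is what keeps the
threshold stable through high-rate episodes, because those cycles fail the
isolated-A3 guard and never enter the histogram.

## 5. Atrial Sensing Setup

Phases run in VDI at the lower rate while the sinus node runs free, so the
A4 sweeps through every cycle phase — including the A3 window — during the
test. Phase 1 (default 20 min) interleaves the four vector combinations
cycle-by-cycle (the collection order is not public). Per spec-level rules
that are not public, these conventions were chosen and exposed as
arguments: "large A4" = median ≥ 1.5 m/s²; initial A4 Threshold = half the
median A4, floored at 1.0; phase-3 A4 Threshold = half the median
post-window A4, clamped to `[0.8, a3_threshold − 0.2]`; Min window end =
Max − 100 ms; phase durations (20, 2, 2) min.

Choices that required judgment:

* **Isolated-A3 guard in VDI.** The ambulatory rate guard (<80 bpm) is
  useless during setup: in VDI the A4's position in the cycle is set by
  pacing phase, not rate. Phase 1 therefore qualifies a cycle as isolated
  only when no AM fired before windowEnd + 40 ms, using the provisional
  device thresholds; an A4 inside the window crosses the provisional A3
  threshold (2.5 m/s² default), fires an AM and disqualifies the cycle.
* **Observed A3 end (phase 1).** The last time the signal exceeds a
  0.5 m/s² perceptibility floor (below the smallest programmable
  threshold), on qualified cycles, masked after any AM; the provisional
  window end is snapped up from its maximum. The initial window is meant
  to be generous — it is the measurement window for phase 2.
* **"Close in amplitude" (phase 2).** Not quantified publicly. Implemented
  as the last time the rectified signal is within a 0.25 m/s² band of the
  phase A4 Threshold, i.e. the last exceedance of `threshold − 0.25` (a
  decaying wavelet leaves the band just after that crossing). The strict
  ≥-threshold alternative degenerates when the initialized threshold sits
  at the ceiling of a patient's A3 distribution: nearly every cycle then
  reports nothing and the window end collapses to a stray measurement.
* **Excluding detected-A4 support (phase 2).** One-sided: everything from
  60 ms before the AM to the end of the cycle is masked. When the variant
  cannot detect the in-window A4 at all — the first generation's finalized
  A3 threshold is far above any A4 — no mask applies and the sweeping A4
  extends the measured "last A3" toward the initial window end. This
  undetected-A4 contamination, not the threshold difference on the A3 tail
  itself, is the dominant reason the first generation programs longer
  windows here, mirroring the clinical observation that its windows were
  often long enough to take in the A4.
* **Scan ceiling.** Setup measurements stop at 1125 ms: the programmable
  window end tops out at 1100 ms, and a following cycle's A4 rising over
  the pace boundary would otherwise leak into the measurement.

Phase 3 is identical in both variants. Variant differences are exactly
two: the finalized A3 Threshold (max + margin vs isolated 95th percentile
+ margin) and the phase-2 threshold (fixed 1.2 m/s² vs the initialized A4
Threshold).

A known edge: for a patient whose isolated-A3 ceiling lies below the
phase-2 measurement level, few cycles yield a measurement and the window
end rests on sparse data; the flagged-defaults path
(`pvab + 50`, `pvab + 150`) covers the fully degenerate case.

## 6. Metrics and statistics

AVS matches each P-wave to the *first subsequent* ventricular event
(matching the "followed by" wording, not nearest-V); synchrony is a delay
≤ 300 ms; PVC cycles (no P) are excluded from the denominator, as are
trailing P-waves with no ventricular event. Rate bins come from the
preceding P-P interval: {<60, 60–70, 70–80, 80–90, 90–100, ≥100} bpm with
80–100 aggregated for the headline comparison. McNemar's test uses the
exact two-sided binomial for fewer than 25 discordant pairs and the
continuity-corrected chi-square otherwise. Survey medians use the
first-bin-past-50 % rule on the four response bins with midpoints
2.5/7.5/15.5/25 min; the open-ended ">20 min" midpoint never carries a
median in the data used. Cohort confidence intervals use a seeded
patient-level bootstrap (2000 resamples) rather than GEE regression, which
is out of scope.

## 7. Reproducibility and scale

Every stochastic path draws from an explicit seed; `with_seed()` restores
the caller's RNG state, so library calls never perturb a session's stream.
Schedules, setup results and event logs are bit-for-bit reproducible from
(script, seed). The acceptance script compresses the stated world to desk
scale — 60-min ambulatory sessions with 20-min "hours" and 15-min "days",
10-min post-setup sessions — and says so; phase durations for the setup
comparison stay at the stated (20, 2, 2) min. The shipped 30-patient
cohort is a fixed artifact (seed 101).

## 8. Known limitations

* Single-lobe Ricker components decay far faster than real oscillatory
  A3/A4 signals, so within-cycle threshold effects are weaker than in
  life; between-variant window differences ride on amplitude selection and
  A4 contamination instead.
* Binary A7 summation flatters high-rate detection of borderline A7s.
* Beat-parameter independence ignores electromechanical coupling.
* The first-generation threshold algorithm and several setup internals are
  behavioral emulations of publicly described behavior, not
  re-implementations.
* Absolute cohort percentages are properties of the synthetic archetypes;
  only directions and mechanisms are claimed.
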