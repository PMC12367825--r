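# avsim

A desk-scale virtual-patient bench for the atrioventricular-synchrony (AVS)
algorithms of accelerometer-sensing leadless pacemakers.

## The problem

A leadless pacemaker implanted in the right ventricle can deliver
AV-synchronous (VDD) pacing without an atrial lead by detecting the
*mechanical* atrial contraction with its built-in accelerometer. The
intracardiac accelerometer signal shows four deflections per cardiac cycle,
A1–A4 (analogous to heart sounds S1–S4): A1/A2 accompany the ventricular
contraction and are blanked by the post-ventricular atrial blanking period
(PVAB), A3 is passive ventricular relaxation, and A4 is the atrial
contraction — the signal the device must track. Detection uses two
thresholds separated in time by the **A3 Window End**: a high **A3
Threshold** inside the A3 window (sit above the A3, catch only large
signals) and a low **A4 Threshold** after it. Above roughly 80 bpm the A3
and A4 superimpose into a summated **A7** signal inside the A3 window, and
everything hinges on the A3 Threshold being above the isolated A3 but below
the A7.

`avsim` reconstructs, as an open simulator, the kind of virtual-patient
bench used to evaluate two generations of the automatic algorithms that
program these parameters:

* **Atrial Sensing Setup** — a three-phase, primarily VDI test that chooses
  the accelerometer vector combination, A3 Threshold, A3 Window End and A4
  Threshold. The second-generation variant ("AV2") learns the *isolated* A3
  amplitude and measures the A3 end with its patient-specific A4 Threshold;
  the first generation ("AV") uses the maximum observed A3-window amplitude
  and a fixed 1.2 m/s² phase threshold, which tends to select long windows
  and high thresholds.
* **Automatic A3 Threshold** — the first-generation per-cycle adaptive rule
  (emulated) ratchets upward during sustained high-rate episodes because it
  tracks the A7-contaminated window maximum, causing A7 undersensing; the
  second-generation "Auto+" rule bins isolated-A3 amplitudes into a daily
  histogram and once per "day" sets the threshold to the 95th percentile
  plus a programmable margin (nominal 1.0 m/s²).

## The model

Every accelerometer deflection is a Ricker wavelet with peak frequency
*f* = 20 Hz:

    w(t) = [1 − 2π²f²t²] · exp(−π²f²t²)

scaled by a per-beat amplitude drawn from a truncated normal distribution
and placed by a timing model (A2 starts 300 ms after the ventricular event,
A4 starts 90 ms after the P-wave onset, the A3 ends at a scripted A3 Signal
End with optional Gaussian jitter of SD 17 or 33 ms). When the A4 begins
before the A3 end the two wavelets are summed sample-wise — the binary A7
rule. Traces are rectified; the device state machine (PVAB 550 ms, upper
tracking rate 105 bpm, lower rate 50 bpm, rate-adaptive A3 Window End on a
25 ms grid) senses the first threshold crossing per cycle and paces. A
cardiac cycle is scored *synchronous* when a ventricular marker follows the
P-wave onset by ≤ 300 ms; cohort comparisons use McNemar's paired test on
the proportion of patients above 70 % AVS.

Two interchangeable engines run the state machine: a dense engine that
scans fully synthesized 1 kHz traces, and an analytic event-level engine
that evaluates the wavelet sum only where component supports intersect the
sensing windows. They agree to within one sample period and the fast one
makes multi-hour cohort simulations desk-scale.

Because the original study's per-patient ambulatory recordings are
proprietary, `make_synthetic_cohort()` generates scripts from three
archetypes (well-separated, A7-undersenser, A3-oversenser) that reproduce
the documented failure modes; headline percentages are therefore
*directional*, not record-for-record reproductions.

## Worked example

```r
library(avsim)
cohort <- make_synthetic_cohort(30, seed = 101)
vp <- cohort[[2]]                       # an A7-undersenser archetype

run_setup("AV",  vp, seed = 11)
#> <avs_setup_result> variant=AV combo=1+2 A3thr=8.31 A4thr=2.44 window=[725, 825] ms
run_setup("AV2", vp, seed = 11)
#> <avs_setup_result> variant=AV2 combo=1+2 A3thr=3.28 A4thr=2.45 window=[675, 775] ms
```

Both variants find the same (strongest-A4) vector combination, but the
second generation programs a 3.3 m/s² A3 Threshold where the first
generation — whose measurement is contaminated by the A4 sweeping through
the window during the VDI test — programs 8.3 m/s², and its Max A3 Window
End is 50 ms shorter.

A paired one-hour ambulatory session (20-min rest, then a sustained
~90 bpm episode; 15-min "days" so the daily update runs at desk scale):

```r
cfg <- device_config(a3_window_end_min_ms = 700, a3_window_end_max_ms = 800,
                     a3_threshold = 3.5, a4_threshold = 2.0,
                     day_length_min = 15)
sch <- generate_session(vp, duration_min = 60, vector_combo = vp$best_combo,
                        seed = 11, hour_length_min = 20)
compute_avs(run_session(cfg, sch, threshold_algo = "auto",     seed = 12))
#> <avs_report> overall AVS 75.7% over 4202 cycles; 80-100 bpm: 45.2% (n=1760)
compute_avs(run_session(cfg, sch, threshold_algo = "autoplus", seed = 12))
#> <avs_report> overall AVS 98.3% over 4202 cycles; 80-100 bpm: 99.4% (n=1760)
```

The per-cycle adaptive threshold ratchets above the A7 amplitude during the
high-rate episode and loses more than half of the 80–100 bpm cycles; the
daily-histogram threshold, set from isolated A3 cycles at rest, keeps
detecting the A7 and preserves synchrony — the mechanism behind the
second generation's high-rate AVS improvement.

Survey arithmetic (from published device-check response percentages):

```r
survey_summary(list(AV = c(11, 29, 30, 30), AV2 = c(51, 35, 14, 0)))
#> median bins "11-20" vs "<5" min; midpoints 15.5 vs 2.5 min
#> saving_min = 13, hours_saved_per_100 = 21.7
```

## Command line

```sh
Rscript -e 'avsim::avsim_cli()' make-cohort --n 30 --seed 101 --out cohort/
Rscript -e 'avsim::avsim_cli()' setup    --script cohort/VP02.json --seed 1 --out setup.json
Rscript -e 'avsim::avsim_cli()' simulate --script cohort/VP02.json --algo autoplus --seed 7 --out log.csv
Rscript -e 'avsim::avsim_cli()' compare  --n 30 --seed 1 --out report
Rscript -e 'avsim::avsim_cli()' survey   --counts inst/extdata/survey_counts.csv --out survey.json
```

Every command writes a run manifest (config snapshot, input digests, seeds)
so outputs reproduce bit-for-bit.

## Scope

The hardware bench (simulator box, hybrid adaptors, programmer), EGM/ECG
morphology, automatic PVAB, rate-response pacing and GEE regression are out
of scope; see `vignettes/avsim-methods.Rmd` for the model's assumptions,
tunable parameters and known limitations.
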