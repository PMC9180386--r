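---
title: "somnoscore: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnoscore: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscore)
```

## The problem

Stimulation-based therapy for obstructive sleep apnea needs two decisions
made continuously and autonomously: *is the patient asleep?* (stimulating
an awake patient is the failure mode to avoid, so false "sleep" calls are
capped, not merely minimized) and *is a respiratory event happening now?*
Both decisions must come from a small sensor set with arithmetic simple
enough for an embedded device: band-pass filters, FFT magnitude sums,
sliding-window extrema, and threshold comparisons. `somnoscore` implements
that pipeline, the per-patient calibration procedure it requires, the
epoch-level evaluation metrics, and a synthetic signal generator that
provides ground truth for every stage.

## Staging model and assumptions

The staging channel statistic is the accumulated FFT magnitude of the
band-passed signal within each 30-s epoch. The underlying physiological
assumptions are:

* alpha-band (8–13 Hz) EEG power is higher in relaxed wakefulness than in
  sleep, most reliably over occipital derivations with eyes closed;
* chin-EMG power (24–45 Hz) is higher awake than asleep through muscle
  tone and movement;
* a *drop below threshold* therefore signals sleep. The decision is
  strict: an epoch with power exactly equal to the threshold is scored
  awake. Strictness matters because the FPT is defined as the *largest*
  threshold keeping false positives under the cap — the sleep region must
  shrink monotonically as the threshold falls, and the boundary must be
  deterministic.

Classification is per channel, then OR-combined: the union errs toward
"sleep" whenever any channel says sleep. This raises sensitivity at the
cost of compounding per-channel false positives, which is why the
channel-combination search (nine fixed sets, from all-EEG to single-region
EEG + EMG) matters: fewer, more reliable channels in the union often beat
the full set. Ties between combinations break toward the earlier set in
the fixed (i)–(ix) order, making the search deterministic.

### Calibration

The ROC scan evaluates exactly 100 thresholds equally spaced between the
channel's minimum and maximum epoch power. Two thresholds are kept per
channel:

* **ROT**, maximizing Youden's J. The underlying ROC "optimum" is not
  otherwise pinned down by the staging problem; Youden's J is the standard
  choice and ties break toward the smallest scanned threshold.
* **FPT**, the largest scanned threshold with false-positive count
  *strictly* below `fp_rate × n_awake` (default cap 10% of expert-awake
  epochs). Strict inequality makes the cap a guarantee, not a target; at
  the minimum scanned threshold the false-positive count is zero by
  construction, so any positive cap is satisfiable (a zero cap falls back
  to the minimum threshold with a warning).

The FPT-vs-ROT transfer regression is fitted on *normalized* coordinates —
each channel-record's ROT and FPT divided by that channel-record's maximum
scanned power — pooled across the six EEG channels of all records (one
regression) and across the two EMG channels (another). EEG points with
normalized ROT above 0.6 are excluded before fitting: empirically those
arise from low-AUC channel-records whose calibration is unreliable, and
the retained fraction is reported alongside the fit. No cutoff is applied
to EMG. The regression is ordinary least squares; R² is the coefficient of
determination on the fitted set. Predicted FPTs are clipped to
`[0, power_max]`.

Whether the regression should be fitted on raw or per-record-normalized
values is genuinely open; this package normalizes per channel-record
because the two thresholds of different records live on incomparable
amplitude scales, and the transfer target (a new patient's FPT from their
ROT) only makes sense on a common scale.

## Filtering and numerical choices

* **Filter design.** Parks–McClellan equiripple FIR (via `signal::remez`),
  pass bands 8–13 Hz (EEG) and 24–45 Hz (EMG), transition width 0.5 Hz,
  passband ripple ≤ 1 dB, stopband attenuation ≥ 40 dB (a typical EEG
  practice figure; the attenuation is a parameter of `design_bandpass()`
  and recorded in the returned filter's attributes). The order is
  estimated from the attenuation/transition-width formula and grown until
  the *measured* response meets spec; an infeasible spec errors, reporting
  the achieved ripple. At 200 Hz the standard EEG filter lands near 800
  taps with ±0.26 dB ripple and ≥50 dB attenuation. The design targets
  half the allowed ripple so that the two-pass (zero-phase) application
  below still sits within the single-pass budget.
* **Zero-phase application.** Filtering is forward–backward, implemented
  exactly as one FFT convolution with the symmetric kernel
  `conv(b, rev(b))` with the group delay removed. A causal single-pass
  filter with ~800 taps would smear band power 2 s across epoch
  boundaries; zero-phase keeps each epoch's power attributed to the epoch
  where it occurred. Record edges carry a transient of one filter length;
  at 4 s against multi-hour records this is negligible and edge epochs
  are not special-cased.
* **Band power.** The per-epoch FFT uses the raw 6000-sample block (no
  window). Frequency bins spaced 1/30 Hz; the accumulated magnitude sums
  bins inside the band, inclusive of the edges, positive frequencies only.
* **AUC.** Trapezoidal area over the scanned (FPR, sensitivity) points
  augmented with (0,0) and (1,1). Against the exact pairwise
  (Mann–Whitney) computation the 100-point scan agrees to ~1e-3 on
  200-epoch records (asserted in the tests at 0.01).
* **Degenerate inputs.** Single-class hypnograms error naming the missing
  class; constant artifact-channel signals (zero amplitude range) warn and
  flag nothing; an expert hypnogram shorter than the recording truncates
  the recording with a warning.

## Respiratory event scoring

The envelope is max − min within a 5-s window (covering one full breath at
the typical 3–5-s respiratory period) advanced in 0.5-s steps: 60 points
per epoch. Windows that would cross the record end are dropped. When the
window is an exact multiple of the step (the default 10×), the
implementation computes per-step block extrema once and takes running
extrema over 10 blocks — algebraically identical to the direct computation
(asserted against brute force in the tests) and an order of magnitude
faster.

Scoring is strictly *within-epoch*: each epoch is compared to its own
previous-epoch baseline ⟨A_{i−1}⟩, and runs are searched inside the
epoch's 60 points. A consequence, documented behavior rather than a bug:
an event crossing an epoch boundary is scored in the epoch(s) where its
qualifying run lives, and may split. Ratio bands are disjoint —
apnea < 0.1, hypopnea (0.1, 0.7] — so a sustained reduction maps to at
most one event kind; the hypopnea band is closed at 0.7 and open at 0.1 to
keep the partition exact. Duration thresholds are ≥ 10 s for both kinds
(20 envelope points); the desaturation criterion is ≥ 3.0 percentage
points of epoch SpO₂ range, in the same epoch as the flow reduction.
Central classification requires *both* effort channels (thorax and
abdomen) below 20% of their own epoch envelope maximum for ≥ 10 s
overlapping the event — the conjunction is the conservative reading, and a
missing effort channel demotes the event to obstructive with a warning
rather than guessing central.

Artifact handling targets ADC saturation: a sample in the top or bottom 1%
of the channel's full-record amplitude *range* marks its whole epoch
unusable. When the channel's ADC limits are declared, a band is only
active if the corresponding extreme actually reaches the rail — otherwise
a clean channel would always lose the epochs containing its natural
extremes. Unusable epochs are excluded from scoring, from baselines (the
following epoch becomes unscorable too), and from every evaluation count.
Artifact flagging is idempotent and composes across channels by
intersecting usable masks.

## The synthetic generator

`generate_psg()` emulates exactly the features the pipeline keys on:

* EEG: unit-RMS pink-noise background plus an independent narrowband
  8–13 Hz component per channel (filtered white noise, not a pure tone, so
  the band-power accumulation is exercised over many bins) with amplitude
  3 in awake epochs and 1 in sleep epochs by default — a 3:1 contrast;
* EMG: band-limited 24–45 Hz noise, RMS 3 awake / 1 asleep;
* epoch-level amplitude jitter: one log-normal draw per epoch (SD 0.1)
  *shared by all channels of a family*, modeling vigilance-state
  fluctuation, which is common across derivations; channel-specific
  variation enters through each channel's own noise realization;
* flow: a sinusoid at the breathing period (default 4 s, valid range
  3–5 s), scaled to the event's amplitude ratio inside injected events.
  The suppressed interval is the nominal duration plus one envelope window
  (5 s), centered in the epoch, so the detector's qualifying run spans the
  nominal duration — the envelope of a partially suppressed window still
  sees full-amplitude breaths;
* effort: breathing-locked sinusoids, suppressed to `effort_fraction`
  (default 0.1) during central apneas only;
* SpO₂: 97% baseline with a trapezoidal 15-s dip of the requested depth in
  the event's epoch (only the epoch max − min matters to the detector, so
  the dip shape is a free choice);
* artifacts: a 1-s burst pinned to the flow channel's ADC rail in the
  requested epochs, with ADC limits declared on all respiratory channels.

Default condition choices: records default to 30% awake epochs (the
worked-example record of the evaluation data has 350/1222 ≈ 29%), sampling
rate 200 Hz, and the default contrasts put per-channel ROC AUC near 1 —
above the >0.8 regime reported for real records, which is the intended
margin for rule-exactness tests rather than a claim about clinical data.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: EEG microstructure (spindles, K-complexes,
artifacts from electrode displacement), eyes-open wakefulness where alpha
is absent and only EMG is informative, cardio-respiratory coupling,
paradoxical thoraco-abdominal motion in obstructive events, arousals, and
oximeter lag. Clinical success rates will be lower than synthetic ones;
the synthetic suite verifies rule exactness and calibration machinery, not
clinical performance.

Validation inside the generator: event tables are checked for one event
per epoch, kind-consistent ratios, and fit within the epoch; events in
epoch 0 (unscorable — no baseline) warn; after synthesis a self-check
recomputes the flow envelope and warns if any injected event's realized
ratio violates its band.

## Evaluation conventions

Confusion counts are epoch-level and always carry an explicit positive
class, because both conventions are in legitimate use: the staging
narrative defines FP/FN with sleep as positive (an FP is an erroneous
"sleep" call), while summary sensitivity/specificity pairs for the same
table are often quoted with awake as positive. `confusion()` supports
both; swapping the class swaps (sensitivity, specificity) and (FP, FN)
consistently, and the success rate (TP+TN)/N is invariant. Zero-denominator
metrics return `NA` with a warning — undefined, never silently 0. Event
evaluation is per-epoch (an epoch is event-positive if any event overlaps
it), restricted to obstructive apneas and hypopneas, since central apneas
follow a different clinical pathway; unusable epochs never contribute to
any count.

## Problem sizes in the test suite

The tests run synthetic records of 5–30 minutes for rule-exactness and
I/O, ten 2-h records for the stochastic staging-recovery check, and a
120-point pooled cohort for regression recovery — sizes chosen so the
complete suite exercises every path, including the multi-seed stochastic
checks, in a few minutes on one core while keeping every statistical
assertion well-powered (a 2-h record has 240 epochs; ten seeds give the
min-over-seeds statistic a real chance to catch calibration regressions).

## Known limitations

* Awake/sleep only; no N1/N2/N3/REM discrimination.
* Hypopneas are desaturation-defined; arousal-based hypopneas without
  desaturation are invisible to the flow+SpO₂ rule by design.
* No mixed-apnea category; the central/obstructive split is binary.
* Events crossing epoch boundaries may split (within-epoch scoring).
* The EDF writer quantizes to 16-bit against the declared ADC (or data)
  range: integer-valued signals round-trip exactly, floats to within one
  quantization step. The per-channel CSV dialect round-trips floats to
  full precision and is the format of choice for fixtures.
* EEG-channel artifacts are not flagged (the 1%-range rule is applied to
  flow, effort, and SpO₂, where saturation artifacts concentrate); how to
  treat EEG artifacts in staging is left unresolved.
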