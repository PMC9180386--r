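# somnoscore

Autonomous awake/sleep staging and apnea/hypopnea scoring from
polysomnography (PSG) signals.

Obstructive sleep apnea (OSA) therapy devices that stimulate the airway
dilator muscles need an on-board algorithm that (a) knows when the patient
is asleep — stimulating an awake patient is unacceptable, so false "sleep"
calls must be tightly capped — and (b) detects apnea and hypopnea events as
they happen, from a minimal set of sensors with computations simple enough
for a wearable microcontroller. `somnoscore` implements such a two-part
pipeline as a tested R library with a command-line interface, plus a
synthetic PSG generator so that every stage can be exercised and validated
without patient data.

## The method

**Part 1 — awake/sleep staging.** Alpha-band EEG activity (8–13 Hz) and
chin-EMG tone both drop at sleep onset. For each of the six EEG derivations
(O1, O2, F3, F4, C3, C4; average-referenced) and two chin-EMG channels, the
signal is band-pass filtered with a linear-phase equiripple FIR filter
(EEG 8–13 Hz, EMG 24–45 Hz, 0.5 Hz transition bands, ≤1 dB passband ripple,
≥40 dB stopband attenuation at 200 Hz sampling), split into 30-s AASM
epochs, and reduced to one number per epoch: the accumulated FFT magnitude
inside the pass band. An epoch is scored *sleep* when that accumulated
power falls strictly below a per-channel threshold.

Thresholds are calibrated per patient against an expert hypnogram
(W/N1/N2/N3/REM collapsed to awake/sleep). A scan of 100 equally spaced
thresholds between the channel's minimum and maximum power yields, per
channel:

* **ROT** — the ROC-optimal threshold (maximum Youden's
  J = sensitivity + specificity − 1), and
* **FPT** — the largest threshold whose false-positive count (awake epochs
  scored sleep) stays strictly below 10% of the expert-awake epochs.

Pooling normalized (ROT/power_max, FPT/power_max) pairs across channels
and records gives a linear regression FPT′ = a·ROT′ + b (EEG points with
ROT′ > 0.6 excluded; these come from low-AUC series) that transfers the
false-positive-capped calibration to new recordings from their ROT alone.
The eight per-channel binary stage series are then OR-combined; nine fixed
channel combinations — (i) EEG, (ii) EMG, (iii) EEG+EMG, (iv) occipital
EEG+EMG, (v) frontal EEG+EMG, (vi) central EEG+EMG, (vii)–(ix) pairs of
EEG regions +EMG — are scored by success rate (TP+TN)/N and the best one
is kept.

**Part 2 — respiratory event scoring.** The nasal-pressure flow signal is
reduced to an amplitude envelope A_i(t): max − min within a 5-s sliding
window (one full breath, periods 3–5 s) advanced in 0.5-s steps — 60
points per epoch. Each epoch i is compared against its baseline
⟨A_{i−1}⟩, the mean envelope of the previous epoch:

* **apnea**: A_i(t)/⟨A_{i−1}⟩ < 0.1 sustained ≥ 10 s;
* **hypopnea**: 0.1 < A_i(t)/⟨A_{i−1}⟩ ≤ 0.7 sustained ≥ 10 s, with an
  SpO₂ desaturation (epoch max − min) ≥ 3 percentage points in the same
  epoch;
* an apnea is **central** when both thoracic and abdominal effort
  envelopes stay below 20% of their own epoch maximum for ≥ 10 s
  overlapping the event, otherwise **obstructive**.

Epochs where the flow, effort, or SpO₂ channel enters the top or bottom 1%
of its amplitude range at a saturated ADC rail are "unusable" and excluded
(epoch 0 and epochs following an unusable epoch have no baseline and are
likewise unscored).

## Worked example

```r
library(somnoscore)

ev <- synth_events(
  kind = c("obstructive_apnea", "central_apnea", "hypopnea"),
  epoch_index = c(5, 12, 20)
)
sim <- generate_psg(synth_spec(duration_sec = 1800, events = ev, seed = 42))

cal <- calibrate_record(sim$recording, sim$hypnogram)
glance(cal)
#>   n_channels combination_id combination_success mean_auc fp_rate
#> 1          8 i                            0.983        1     0.1

staging <- stage_record(sim$recording, cal, combination = "iv")
glance(confusion(staging$sleep, binarize_stages(sim$hypnogram)))
#>   sensitivity specificity success_rate fp_accuracy  n positive_class
#> 1           1       0.833         0.95        0.95 60 sleep

sc <- score_record(sim$recording)
sc$events
#>   onset_sec duration_sec type              epoch_index min_ratio desat_points
#> 1      156.         12.5 obstructive_apnea           5    0.0685        NA
#> 2      366.         12.5 central_apnea              12    0.0686        NA
#> 3      606.         14.5 hypopnea                   20    0.507         4.38

glance(event_confusion(sc$epoch_flags, sim$events, sc$grid))
#>   sensitivity specificity success_rate fp_accuracy  n positive_class
#> 1           1           1            1           1 60 event
```

Staging is read as: every expert-sleep epoch was recovered
(sensitivity 1), three awake epochs were falsely scored sleep
(specificity 0.833 on 18 awake epochs), overall success rate 0.95 — the
deliberate trade of the 10% false-positive cap, which maximizes sleep
coverage subject to the awake-protection constraint. All three injected
respiratory events are recovered at their epochs with the right subtype
and measured amplitude ratios close to the injected 0.05 / 0.5.

The command-line interface wraps the same functions:

```sh
inst/cli/somnoscore simulate  --out sim --duration 1800 --seed 42
inst/cli/somnoscore calibrate --input sim/record_01/signals \
    --hypnogram sim/record_01/hypnogram.csv --out cal.txt
inst/cli/somnoscore stage     --input sim/record_01/signals \
    --calibration cal.txt --out stages.csv
inst/cli/somnoscore detect    --input sim/record_01/signals --out events.csv
inst/cli/somnoscore evaluate  --staging stages.csv \
    --hypnogram sim/record_01/hypnogram.csv --out metrics.csv
```

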