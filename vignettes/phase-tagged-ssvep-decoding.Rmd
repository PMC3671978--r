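---
title: "Decoding phase-tagged SSVEPs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding phase-tagged SSVEPs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssvepbci)
```

## The problem

A phase-tagged SSVEP brain–computer interface drives several visual
flickers at one frequency and distinguishes them by phase. With four
targets at 20 Hz the tags are 0°, 90°, 180° and 270°, implemented by
delaying each flicker sequence by `θ/360 × T` (0, 12.5, 25, 37.5 ms).
Occipital EEG phase-locks to the gazed flicker, so the target is read from
the phase of the 20 Hz EEG component; when the user is not gazing, that
phase is uninformative and close to uniform over the full cycle. The
decoder therefore has to answer two questions at once: *is* the user
gazing (rest detection), and if so, *where* (phase classification).

## Signal model and simulator

`simulate_recording()` generates single-channel Oz EEG at `fs` = 1000 Hz:

* gaze at target `c`:
  `A·cos(2π f0 t + θ_c + φ_subject [+ per-cycle jitter]) + noise(t)`
* rest: `noise(t)` alone.

`noise(t)` is stationary Gaussian, band-limited to 0.1–100 Hz (the usual
acquisition pre-filter band) and rescaled to standard deviation
`noise_sd`; an optional 1/f spectral shaping is available but off by
default, since no noise spectrum is specified for the reference protocol.
`φ_subject` is a constant per-subject visual-pathway phase offset, drawn
once per simulated subject; per-subject variability is spanned by the
triple (`subject_phase_offset`, `ssvep_amplitude`, `noise_sd`). The SSVEP
is a single sinusoid at `f0`: the decoder only inspects 20 Hz and the
17–23 Hz band-pass removes harmonics, so modelling them would not change
any downstream quantity.

Defaults: `ssvep_amplitude` = 1 µV and `noise_sd` = 1.25 µV. No
signal-to-noise ratio is published for the reference subjects, so the
noise default was calibrated once, by a coarse sweep, to place held-out
per-vector classification accuracy near the mid-90% range reported for
real subjects; it was fixed before the acceptance checks were written and
not revisited. `simulate_online_session()` emulates the cued protocol:
`S × n_trials_per_class` trials (default 4 × 20 = 80) in seed-randomized
order, each a 0.5 s gaze-shift transition (noise only — eye-movement
artifacts are not modelled, only the absence of locked signal) followed by
`gaze_s` = 4 s of phase-locked signal. Trial boundaries sit on the flicker
cycle grid so that windows stay trigger-locked across trials.

What the simulator deliberately does **not** model: within-recording phase
drift (attention, fatigue, stimulator drift), eye-blink/EMG artifacts,
multichannel structure, non-stationary noise. Consequences for
interpreting green tests are discussed under *Limitations*.

## Feature extraction

The recording is filtered with a causal (forward-only) Butterworth
band-pass, 17–23 Hz. "6th order" is read as the overall band-pass order
(a 3rd-order low/high prototype), the convention under which
`signal::butter(3, c(17, 23)/500, "pass")` returns a 6th-order filter; the
per-edge reading would double the order and is not used. Filtering runs
causally from zero initial state — an online decoder cannot use zero-phase
refinement — so every phase acquires the same group-delay constant, which
the classifier absorbs. No start-up span is discarded offline.

Each 4-cycle window (K = 200 samples; 75% overlap, i.e. one-cycle steps of
50 samples) yields one input vector via the Hamming-weighted single-bin
Fourier sum

`F_i = (1/K) Σ_{n=1..K} w[n] s_i[n] e^{−j2π(f0/fs)n}`, `x_i = [|F_i|, ∠F_i]`,

with `w[n] = 0.54 − 0.46 cos(2πn/(K−1))` and the `1/K` normalisation kept
as-is (no coherent-gain correction — the absolute amplitude scale is
irrelevant to classification, and tests assert the implied scale
`Σw/2K ≈ 0.269` for a unit sinusoid). A 30 s recording gives exactly
`floor((30000 − 200)/50) + 1 = 597` vectors. Offline windows are aligned
to the recording start, online windows to the reference (target 1) trigger
grid; the two differ only by a common phase rotation. Flicker onset times
are computed in continuous milliseconds and rounded **half-up** to the
1 kHz sample grid (so the 12.5 ms tag lands on sample 13); the rounding
convention is ours — the stimulator operates in continuous time and any
fixed convention only shifts all phases by a sub-sample constant.

## Classifier

Gaze-class training vectors are screened by a two-sided Z-test at
α = 0.05 on each feature: the amplitude z-score against the class mean/SD,
and the angular deviation from the class circular mean scaled by the
circular SD (`√(−2 log R)` in degrees). A vector is dropped if either test
rejects. The test statistic is our reading — the protocol names a Z-test
without defining its statistic — so every exclusion is logged
(`attr(, "exclusion_log")`) for audit. The resting class is not cleaned;
outlier removal against a uniform phase distribution is ill-posed. A class
feature with zero spread skips that test with a warning rather than
dividing by zero.

The multiclass machine is one-against-all: one binary RBF-kernel SVM per
class (4 gaze + rest = 5 machines), prediction by argmax of the decision
values, ties resolved toward the lower class index with rest last. No
kernel or hyperparameters are published for the reference system; the
defaults are an RBF kernel with `cost`/`gamma` chosen by 3-fold
cross-validated grid search (cost ∈ {1, 10, 100}, gamma ∈ {0.05, 0.5}) on
multiclass accuracy, all selections recorded in the model object and
overridable. Features are standardised with training-set statistics inside
each binary machine — required in a scale-mixed (µV, degrees) space. Phase
is fed raw in degrees, faithful to the 2-D feature definition; an optional
`(A cos φ, A sin φ)` encoding removes the 0°/360° seam for users who want
it. One upstream quirk worth recording: the binary-SVM backend orients
decision values by the order labels appear in the *data*, not by factor
levels, so the package normalises the sign from the returned column name.

## Effective epochs and voting

Rest detection uses the discrepancy between concentrated gaze phases and
uniform rest phases. An epoch starts at Z = 10 vectors and grows by one
vector while the one-sample Kolmogorov–Smirnov test against U(0°, 360°)
fails to reject at α = 0.01; the first rejecting prefix is the effective
epoch. The p-value uses the exact small-sample Kolmogorov distribution up
to n = 100 (epoch sizes live well below this) and the asymptotic series
beyond; ties (identical phases, as in noiseless streams) are legitimate
inputs and only void the continuity assumption behind the exact null, not
the statistic. Sequential testing at a fixed α inflates the overall
false-alarm rate across growth steps; the literal procedure is kept
deliberately, without multiplicity correction. Three terminal states are
distinguished: `epoch` (gate passed), `timeout` (cap reached) and
`no_decision` (stream shorter than Z). The protocol itself sets no
timeout; `max_vectors = 597` (~30 s) is our bound so an online system
terminates, far above observed epoch lengths.

Each epoch vector is classified and the command is the plurality vote;
vote ties break toward the largest decision-value sum over the epoch (and
are flagged). A rest winner or a timeout emits no command. Epoch length in
seconds is accounted from the first window's start to the last window's
end, `(K + (n−1)·step)/fs` — 0.65 s for a 10-vector epoch; start-to-start
accounting would subtract one window. After each command the accumulator
resets and the next trial's first 10 vectors (the 0.5 s transition) are
skipped. Held-out *offline* evaluation uses the same machinery
(`segment_epochs()`): the test half is consumed as consecutive disjoint
voted epochs, which is what makes its accuracy comparable to the 0.7 s
baseline rather than a per-200 ms-window figure.

## Metrics and baseline

`bits_per_command(P, S)` is the Wolpaw formula with `0·log 0 = 0`. It is
0 at chance `P = 1/S`, which is its minimum — it is *not* negative below
chance (at `P = 0`, `S = 4` it equals `2 − log2 3 ≈ 0.415`), a property the
tests pin against a numeric-derivative oracle. `CTI = T_total/n_commands`
and `ITR = bits × 60/CTI`; ITR values are kept at full precision and
rounded to 2 decimals only for table comparison.

The comparison baseline is the classical cycle-average detector: average
`n_cycles = 14` consecutive trigger-locked flicker cycles (detection
interval 0.7 s), read the phase of the averaged 50-sample cycle with a
single-cycle rectangular DFT at `f0` — the averaging *is* the noise
suppression, and Hamming-weighting one cycle would bias the phase — and
assign the nearest phase template (templates are per-class circular means
from a training run). The ±45° margin of the quadrature layout only flags
low-confidence assignments; the published method does not say whether
out-of-margin phases abstain, so nearest-template assignment is kept and
the flag preserved.

## Problem sizes used by the test-suite

The suite regenerates all data in code: 60 s-per-condition studies for the
protocol geometry (597/2985 vectors), 10 000 replicates for the K-S gate's
type-I error, 100 seeds for rest-phase uniformity, a 510 s rest recording
(>10⁴ windows) for the large-sample chi-square check, and a 3 × 2
noise-by-seed grid for the noise-degradation property. These sizes were
chosen to keep Monte-Carlo standard errors well inside the asserted
tolerances.

## Limitations

* **Serial correlation of overlapped windows.** Adjacent 75%-overlap
  windows share 150 of 200 samples, and the narrow 17–23 Hz band extends
  coherence further, so rest-phase *streams* are not i.i.d. A one-sample
  K-S test applied to all 597 overlapped rest phases of a 30 s recording
  over-rejects (measured ≈ 30–40% at α = 0.05 instead of 5%); on
  non-overlapping windows the rate is nominal. The uniformity tests
  therefore check the marginal distribution (chi-square) and decorrelated
  windows (K-S). The sequential online gate inherits the same inflation on
  rest streams — which matches the literal published procedure, not an
  idealised one.
* **The baseline is near-optimal on stationary synthetic data.** Under
  stationary Gaussian noise, coherently averaging 14 trigger-locked cycles
  is essentially a matched filter, and the calibrated-template detector
  matches or exceeds the SVM pipeline at every noise level we measured.
  The advantage reported for adaptive classifiers on real EEG rests on
  non-stationarity — phase drift with attention and arousal, artifacts —
  that this simulator intentionally omits. Consistently, no single
  `noise_sd` reproduces both published accuracy figures (mid-90% for the
  SVM *and* ~70% for the baseline). Passing end-to-end tests here
  demonstrates correctness of the decoding chain, not superiority of the
  classifier over the baseline on real recordings; the suite asserts the
  directional comparison and the assertion documents this gap when it
  fails.
* Online synthetic sessions are cleaner than laboratory sessions (no
  artifacts, no drift), so simulated online ITRs exceed realistic values
  even at a noise level calibrated to realistic offline accuracy.
* The exact K-S null assumes continuous data; with heavily tied phases the
  reported p is conservative in the direction that favours rejection,
  which is the desired behaviour for noiseless gaze streams.
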