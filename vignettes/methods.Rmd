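---
title: "Center-surround apparent-motion integration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-surround apparent-motion integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lateralflow)
```

## The scientific problem

Neurons in primary visual cortex (V1) respond to stimuli inside their
receptive field (RF), but their membrane potential is also modulated by
stimuli flashed in the "silent" surround, relayed laterally through
long-range horizontal axons. Because horizontal conduction is slow (a few
tenths of a millimetre of cortex per millisecond), a surround stimulus at
eccentricity $e$ degrees evokes a subthreshold postsynaptic potential (PSP)
whose onset latency grows linearly with $e$ — the *latency basin* — while
its amplitude decays roughly exponentially with distance.

An apparent-motion (AM) sequence of Gabor patches sweeping from the far
surround towards the RF center can, at the right speed, *synchronize* the
lateral volleys it launches with the feedforward volley evoked by the final
center stroke. The working hypothesis embodied in this package is that
centripetal, iso-oriented (CP-ISO) flows at a speed matched to the
horizontal propagation speed produce a latency advance and gain increase of
the cell's response, whereas centrifugal, cross-oriented, or
spatio-temporally randomized flows do not.

`lateralflow` implements the complete computational chain around this
hypothesis: stimulus-protocol construction, a trial-level synthetic
membrane-potential generator, trace conditioning, permutation statistics,
linear predictors, propagation-speed estimation, and population summaries.
No recorded data ship with the package; the generator makes every
downstream statistic testable, and parameter recovery is the core
validation surface.

## Stimulus protocols

Two protocol families are built from a cell's RF geometry
(`rf_geometry()`):

* **Cardinal** (`build_cardinal_protocol()`): two- or three-stroke AM
  sequences along the preferred-orientation ("main") and orthogonal
  ("width") axes, one side of the RF at a time. The Gabor mask is 150% of
  the discharge-field length, its envelope s.d. 20% of the mask, the
  inter-node spacing 120% of the mask, and each stroke lasts one 60 Hz
  frame (16.6 ms). The surround-only variant enumerates 8 flows x 2
  directions + Center-Only + Blank = 18 conditions; the center-surround
  variant 4 flows x 2 directions + Center-Only + Blank = 10.
* **Radial** (`build_radial_protocol()`): five concentric rings spaced by
  the full extent of the subthreshold depolarizing field (SRF), so the
  nearest ring does not encroach on the SRF; 30 ms strokes by default. A
  block holds 16 AM sequences (CP-ISO, CF-ISO, CP-CROSS, RND-ISO x with or
  without the terminal center stroke x SECTOR/FULL), 21 isolated-patch
  stimulations (5 rings x ISO/CROSS x SECTOR/FULL + 1 center patch) and 6
  blanks: 43 entries, presented once each per block in seeded random
  order.

```{r counts}
rf <- rf_geometry(mdf_length = 2, mdf_width = 1, srf_extent = 5)
n_conditions(build_cardinal_protocol(rf, "surround_only"))
n_conditions(build_radial_protocol(rf))
```

Design choices worth stating:

* *Flow direction conventions.* Centripetal sequences run far-to-near and,
  in full trajectories, end with the center test stroke; centrifugal full
  sequences start with the center stroke and move outward. The expected
  center time of a surround-only sequence (`center_reference_time()`) is
  accordingly one inter-stroke interval after the last stroke (CP, RND) or
  before the first (CF); all phase and modulation analyses are realigned
  to this reference.
* *Ring population.* The SECTOR configuration places a symmetric pair of
  patches per ring on the preferred-orientation axis; FULL spreads
  patches over eight directions. The per-ring patch counts are
  configurable; printed pool sizes in the source protocols could not be
  reconciled exactly with a fixed angular grid, so layout is exposed as
  configuration rather than hard-coded.
* *Contrasts* default to the protocol means (0.925 surround, 0.406
  center).
* *RND-ISO* (`randomize_sequence()`) permutes the node-to-slot assignment
  under a seed, leaving onsets, durations, features — hence total stimulus
  energy — untouched, and always pins the final stroke to the RF center.

## The synthetic generator

`simulate_trial()` builds a 10 kHz membrane-potential trace as

$$V(t) = V_{rest} + \eta(t) + \sum_i A_i \, k(t - t_i),$$

where $k$ is a double-exponential kernel with unit peak (rise 4 ms, decay
20 ms by default), and each stroke contributes one PSP per patch:

* a **lateral** PSP for surround patches, with onset
  $t_i = t_{stroke} + L_0 + e \cdot M / v$ and amplitude
  $A_i = a_0 e^{-e/\lambda} \cdot c$ (contrast $c$), where $v$ is the true
  apparent speed of horizontal propagation (ASHP, mm/ms), $M$ the cortical
  magnification (mm/degree) and $L_0$ the feedforward base latency;
* a **feedforward** PSP for center strokes, onset $t_{stroke} + L_0$,
  amplitude $A_{ff} \cdot c$.

$\eta$ is an exactly discretized stationary Ornstein–Uhlenbeck process
(s.d. `noise_sigma`, correlation time `noise_tau`); spikes are emitted at
upward threshold crossings with an absolute refractory period and a
stereotyped spike waveform is added so that spike removal can be exercised.

The **supra-linear interaction** is a gated gain: any PSP whose onset is
led by accumulated depolarization from earlier strokes by more than
`interaction_lag_threshold` (5.5 ms) is multiplied by
`1 + interaction_gain`. The gate applies to the feedforward PSP (lateral
lead boosts the center response) and equally to lateral PSPs recruited
late in a coherent flow, which makes surround-only responses supra-linear
relative to the sum of isolated responses — the property the non-linearity
test detects. With `interaction_gain = 0` the model is exactly additive,
which is the ground truth used by the predictor tests.

Default parameter values and why:

| parameter | default | rationale |
|---|---|---|
| `ashp_true` | 0.2 mm/ms | middle of the physiological 0.05–0.60 range, near the modal 0.10–0.30 |
| `base_latency` | 40 ms | typical V1 feedforward PSP onset |
| `magnification` | 1 mm/degree | the value consistent with the printed retinal/cortical speed equivalences for cat area 17 |
| `a0`, `lambda_decay` | 4 mV, 15 degrees | SRF-scale decay leaving the farthest ring (25 degrees) a clearly measurable ~0.7 mV isolated response, as isolated far patches do evoke significant PSPs |
| `ff_amplitude` | 8 mV (unit contrast) | center-only peaks of a few mV at the default 0.406 contrast |
| `noise_sigma`, `noise_tau` | 1 mV, 15 ms | moderate ongoing synaptic noise with a membrane-scale correlation time |
| `v_rest`, `spike_threshold` | −70, −60 mV | resting range of sharp-electrode recordings; sparse spiking at combined drive |

These values define the simulated study conditions once; tests and the
acceptance script run under them (or under explicitly stated priors such
as `ashp_true ~ U(0.1, 0.3)`) rather than retuning per analysis.

What the generator does *not* emulate: conductance-based membrane
dynamics, orientation maps, adaptation, eye movements, or the non-specific
"near-surround" feedforward contamination of the cardinal protocol (an
optional additive term was considered but has no calibrated default). A
soft saturation towards a synaptic reversal potential is available
(`soft_clip`) but off by default. Passing tests therefore certify the
analysis chain under the stated model, not the biophysics of real
recordings.

## Preprocessing

Following the conditioning chain for intracellular traces:

1. **Spike removal** (`remove_spikes()`): spikes are threshold-detected
   (dV/dt criterion by default; no printed value exists, 10 mV/ms is the
   package default) and each spike waveform is replaced by
   $\alpha(t) = a\,t\,e^{-t/\tau}$, with $a$ the slope at the peak of the
   second derivative of the rising phase and $\tau$ the spike half-width,
   spliced with a 1 ms linear blend (the splice rule is a package choice).
   Overlapping spikes are merged into one replacement with a warning.
2. **Conditioning** (`condition_trace()`): zero-phase Butterworth low-pass
   at 300 Hz (zero-phase so latency measures are unbiased), decimation to
   1 kHz, 7 ms sliding average. The nominal 0.1 Hz high-pass edge is
   implemented but off by default: zero-phase sub-Hz filtering of
   sub-second epochs removes a *length-dependent* fraction of the DC level
   and corrupts blank subtraction across entries of unequal duration;
   slow drifts common to blanks and stimulations are removed by the blank
   subtraction itself.
3. **Averaging** (`build_pstw()`, `build_psth()`): mean ± SEM across
   trials; PSTHs are binned at 1 kHz and smoothed with a Gaussian window
   (sigma = 3 ms), in spikes/s, integrating to the mean spike count.
4. **Blank subtraction** (`subtract_blank()`): pointwise, so permutation
   envelopes are centered on zero (and smoothed spike rates can go
   negative). Because all conditioning steps are linear and
   time-invariant, the order of smoothing and blank subtraction is
   immaterial.

## Statistics

* `ztest_threshold_integral()`: baseline mean and s.d. from a 100 ms
  pre-stimulus window; the response is thresholded above the one-sided 95%
  baseline bound and integrated over 0–250 ms (mV·ms, non-negative by
  construction).
* `permutation_envelope()`: pointwise null distribution of the mean
  difference between two trial groups under trial-label permutation
  (10^4 repetitions by default; exhaustive enumeration available for tiny
  groups), with a consecutive-duration criterion (1 ms for surround-only
  screening, 7 ms against the linear predictor, 15 ms as a conservative
  variant). With `calibrate_duration = TRUE` the same permutations also
  yield the null distribution of the longest exceedance run, so the
  duration criterion itself is held to the test level; without it, a
  fixed duration rule plus a pointwise bound has a substantial family-wise
  false-positive rate over a 120 ms window when the noise is slow.
* `screen_responsive()`: a cell enters analysis only if its Center-Only
  response beats the blank at p < 0.01 over 0–120 ms.
* `onset_latency()`: `three_sigma` (first departure from the blank mean by
  3 blank s.d.; used for population realignment) or `half_height`
  (crossing of half the reference peak on the rising phase anchored at the
  waveform's maximum, with linear interpolation). Peak anchoring ignores
  noise excursions disconnected from the response, which matters for weak
  far-surround responses; an optional `sustain_ms` guard additionally
  requires the crossing to persist. Undefined latencies return `NA` and
  are excluded, not imputed, from summaries.
* `contextual_modulation()`: latency change at half-height of the
  Center-Only peak (positive = advance) and the ratio of depolarizing
  envelope integrals, with permutation significance for both. Per-condition
  tests are reported without multiplicity correction, replicating the
  source analyses; an FDR toggle can be applied downstream via
  `p.adjust()` on the results table.

## Predictors and non-linearity detection

The **surround linear predictor** (`surround_linear_predictor()`) is the
sum of blank-subtracted responses to isolated patches, each shifted by its
chronogram onset (zero-padded outside the recorded window; isolated
responses are pooled across blocks). Under the additive generator it
equals the simulated surround-only response to numerical precision.

`nonlinearity_test()` declares a dynamic non-linearity when the observed
surround-only mean exceeds the predictor's upper permutation bound for at
least 7 consecutive ms in 0–120 ms. Two nulls are available:

* a one-sample sign-randomization of observed-minus-predictor residuals,
  appropriate when the predictor is exact (e.g. a closed-form oracle);
* the calibrated default for estimated predictors: virtual predictor
  trials (`slp_virtual_trials()`) built by pairing one isolated trial per
  node *without replacement* and summing, compared to the observed trials
  with the two-sample permutation envelope and the run-length-calibrated
  duration criterion. Pairing without replacement keeps virtual trials
  independent, so the predictor's estimation error is exactly a
  sample-mean error under the permutation null; with-replacement pairing
  or a deterministic predictor substantially inflates the false-positive
  rate.

The **center-subtraction predictor** (`center_subtraction_predictor()`)
is the full "surround-then-center" response minus the Center-Only
response; under the gated generator it exceeds the simulated surround-only
component wherever the feedforward boost is active.

## Propagation analyses

`fit_latency_basin()` regresses surround-only onset latency on
eccentricity (OLS) and converts the slope to a cortical speed,
ASHP = magnification / slope; additive latency offsets are absorbed by the
intercept, and non-positive slopes return an `NA` speed (no propagation
signature). `input_phase()` is the Center-Only minus Surround-Only onset
difference on the common expected-center reference (positive = lateral
input leads). `fit_bilinear()` fits two connex linear segments with the
breakpoint chosen by exhaustive search over observed phases and midpoints
(an independent-halves toggle exists because the source description is
ambiguous between the two); the continuous-hinge SSE is never worse than a
single line's. `kde_density()` wraps a Gaussian KDE with Silverman's
bandwidth.

## Population summaries

`normalize_and_realign()` divides each cell's waveform by its Center-Only
peak, shifts time so the Center-Only three-sigma onset sits at 0, and
resamples on the common 1 kHz grid cropped to the intersection window;
cells with non-positive peaks or undefined onsets are excluded and listed.
Because rise times differ across cells, the population-average peak is
generally below the norm of 1. `speed_tuning_profile()` tabulates peak
contextual amplitude per replay fraction (100/70/50/30% of the nominal
speed), excluding incomplete cells from the ordering statistic.

## Problem sizes and reproducibility

The shipped analyses use 3–5 synthetic cells, 19–50 blocks (20 in the
demo), 5 eccentricities x 20 trials for parameter recovery, 500 Monte
Carlo runs for test calibration, and 10^3 permutations in the demo
pipeline (10^4 in production settings); the demo completes in well under a
minute on one core. All randomness flows from a master seed through named
substreams (`derive_seed()`), so `run_pipeline()` is bit-reproducible for
a given configuration, and dataset containers round-trip losslessly
(`write_dataset()` / `read_dataset()`).

## Known limitations

* The generator's additive/gated-gain structure is the simplest mechanism
  expressing the stated supra-linearity; it does not model
  voltage-dependent conductances, so quantitative interaction magnitudes
  are not transferable to real cells.
* Latency measures assume a single dominant depolarizing peak per window;
  multiphasic responses may need a narrowed search window.
* The radial ring layout treats a ring as the stimulation unit; analyses
  of single off-axis patches require a custom node layout.
* Population headline proportions from the source recordings (fractions
  of facilitated cells, median condition biases) depend on unavailable
  data and are treated as qualitative direction checks on synthetic data
  only.
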