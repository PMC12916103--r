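---
title: "Models and methods behind pvephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pvephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvephys)
```

`pvephys` packages the quantitative procedures used to characterize
fast-spiking, parvalbumin-positive interneuron (PV-IN) physiology and
Kv3 potassium-channel function across five recording modalities. This
vignette is the package's own account of those procedures: the model or
rule each one implements, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and where the design was genuinely open.

## Current-clamp analysis

**Spike detection.** An AP is a local maximum of the membrane potential
that reaches at least −10 mV. The −10 mV floor is the modality's
counting rule; on top of it the detector requires a dV/dt upstroke of at
least 20 mV/ms within the preceding 2 ms and merges peaks closer than
1 ms. The upstroke gate is our addition (configurable, disable with
`upstroke_gate_mV_ms = 0`): a bare peak-floor rule also fires on
stimulus artifacts, and a 20 mV/ms gate is an order of magnitude below
any real somatic upstroke while well above capacitive transients at the
sampling rates involved. Detection is invariant to DC offsets that keep
peaks above the floor.

**Waveform features.** All single-AP features are computed on the first
spike evoked by a 100 pA/s depolarizing ramp (steps can be analysed the
same way; the ramp is the default because the approach to threshold is
slow and unambiguous there). The derivative is a plain central
difference in mV/ms with no pre-smoothing (a boxcar width is exposed but
defaults to 0; at 100 kHz sampling raw differences are stable, and any
smoothing biases the upstroke/downstroke extrema). Threshold is the
voltage at the first sample — scanning toward the peak — where dV/dt
exceeds 5% of the window's maximal upstroke. Amplitude is peak minus
threshold. APD50 is the time spent above threshold + amplitude/2, with
both crossings linearly interpolated between samples; the
half-amplitude level is referenced to threshold rather than to an
absolute half-peak because amplitude itself is defined
threshold-to-peak. The AHP is the absolute minimum of Vm in a 10 ms
post-peak window; the window length is our choice (configurable) — the
defining rule says only "post-spike minimum", and 10 ms comfortably
contains the fast AHP of a fast-spiking cell while excluding the next
spike at steady firing rates below 100 Hz.

**Passive properties and F–I.** Resting Vm is the median of a gap-free
trace (robust to spontaneous spikes occupying a small fraction of
samples). Input resistance is ΔV_ss/I on the −20 pA step, with ΔV_ss
the mean over the last 20% of the step minus the pre-step baseline.
F–I counts spike peaks inside the step interval of 1 s injections from
−100 to 500 pA. Rheobase follows the study convention literally: the
largest step that did **not** evoke spikes. That convention is unusual
(most packages report the smallest spiking step), so `rheobase()`
returns both values; with non-monotonic counts the literal rule is
still applied and the result flagged. All-silent and all-spiking inputs
produce distinct errors rather than extrapolated values.

## Voltage-clamp analysis

Step families (100 ms steps, −80…+40 mV in 5 mV increments from −80 mV
holding for macropatches; −85…+55 mV from −120 mV for heterologous
cells) are baseline-subtracted against the mean of the 5 ms pre-step
window. Peak current is the largest-magnitude excursion during the
step; steady-state current is the mean over the last 10% of the step.
For a non-inactivating Kv3-like current with activation τ ≤ 10 ms the
two agree within 1% at 100 ms.

**Which current feeds the G–V curve** was an open choice. The package
defaults to the peak in `peak_current()`, but the recovery studies in
the test suite use the steady-state mean: a single-sample extremum of a
noisy trace is extreme-value biased upward on every step, which
corrupts the small-conductance limb of the curve, whereas the 10%-tail
mean averages the same noise away and — for a non-inactivating
current — estimates the same quantity. Conductance is
G = I/(V − E_rev) with steps within 1 mV of the reversal dropped,
negative leak-noise values clamped to zero, and the curve normalized to
its maximum. E_rev is computed from the solution recipes via the Nernst
equation rather than assumed (≈ −105 mV for K⁺ under the slice
solutions at 32 °C); a fixed override is available. No P/n leak
subtraction is applied because none is part of the modeled protocol;
baseline subtraction is the default and a linear-leak fit over
hyperpolarized steps remains an escape hatch for real data.

The Boltzmann fit minimizes least squares for
G/G<sub>max</sub> = 1/(1 + exp(−(V − V<sub>½</sub>)/k)) via
Levenberg–Marquardt, initialized with V<sub>½</sub> at the interpolated
half-maximum crossing and k = 8 mV, with k bounded to [0.5, 50] mV. A
residual RMS above 0.05 (normalized scale) raises a quality flag.
Activation kinetics are fit with a single exponential
I(t) = A(1 − e<sup>−t/τ</sup>) from 0.5 ms after step onset (skipping
the clamp artifact) to the time of peak; no sigmoidal delay (power > 1)
is modeled, as the data the procedure targets do not constrain one —
both the window and the model order are configurable. Decaying traces
are rejected rather than fit.

**Solutions and reversal potentials.** `solution_composition()`
assembles total ion concentrations from salt recipes under full
dissociation (e.g. CaCl₂ contributes two chlorides), and
`nernst_potential()` evaluates E = (RT/zF)·ln([out]/[in]) at the
solution temperature. With the chloride-loaded whole-cell internal
(65 KCl + 2 MgCl₂ → 69 mM Cl⁻) against standard ACSF (133.5 mM Cl⁻) at
32 °C this yields −17 mV to the nearest integer, the value that makes
inhibitory currents inward at a −70 mV holding potential.

## Paired-recording analysis

For each presynaptic AP (detected with the current-clamp module), the
postsynaptic search window runs to the next AP or 50 ms, whichever is
first — at 120 Hz the 8.3 ms inter-pulse interval governs. Amplitude is
the deviation of the windowed extremum, in the declared polarity
direction, from a local baseline (mean of the 2 ms before the AP peak);
the local baseline makes amplitudes during summating high-frequency
trains measure the increment rather than the absolute current. An event
must **exceed** 10 pA; exactly 10.0 pA is a failure. Failures enter
amplitude means as 0 pA by default (efficacy reading; a
`failures_as_zero = FALSE` switch gives the potency reading) — the
default keeps paired-pulse ratios well-defined and matches how
"magnitude" is typically reported for trains with failures.
Paired-pulse ratios are ratios of mean amplitudes, not means of
per-sweep ratios, because per-sweep ratios are undefined whenever pulse
1 fails. Onset latency is the first excursion beyond 2× the baseline SD
sustained for 0.5 ms; the sustain requirement rejects single-sample
noise crossings. Both AP-peak-to-onset and AP-peak-to-peak latencies
are reported; the headline number is the onset variant.

Connection probabilities use a two-sided Fisher exact test implemented
by direct hypergeometric enumeration (the sum of all tables with the
observed margins whose probability does not exceed the observed
table's). The test suite cross-checks it against both an independent
factorial-enumeration oracle and `stats::fisher.test`.

## Calcium-imaging analysis

**Baseline.** F₀ for each cell is the 10th percentile of its
fluorescence computed per 1000-frame block, linearly interpolated
between block centres and held constant beyond the first and last
centre; a tail block shorter than 1000 frames gets its own percentile.
An alternative reading of the same rule — block means of a rolling
percentile — is implemented behind `rolling = TRUE`; the per-block
percentile is the default because it is the simpler construction
consistent with the rule's wording. dF/F₀ = (F − F₀)/F₀ is exactly
invariant to positive rescaling of F and identically zero on constant
traces; non-positive baselines are an error with guidance rather than a
silent NaN.

**Discharges.** Field-of-view hypersynchronous discharges are peaks of
the z-scored, 1 Hz-high-passed (2nd-order Butterworth, zero-phase) FOV
mean with z > 5 and ≥ 1 s separation. The separation is our addition to
avoid double-counting multi-peaked events; constant traces return no
events instead of dividing by a zero SD.

**Transients.** Per-cell transients are peaks of the moving-mean
smoothed (5 frames ≈ 167 ms at 30 Hz; width configurable, the defining
rule does not state one), z-scored trace with z ≥ 1, prominence ≥ 0.5 z
and ≥ 200 ms between kept peaks (taller peaks win); times are refined
to the unsmoothed maximum within half a smoothing window. The z-score
reference is the mean/SD of the cell's full smoothed trace; a robust
median/MAD variant is available. This threshold set is deliberately
permissive: because the z denominator includes the transients
themselves, the effective height threshold scales with how
signal-dominated the trace is, and on noise-dominated traces a z ≥ 1
rule admits noise peaks. That is precisely why the procedure is paired
with `threshold_robustness_sweep()`, which re-runs detection over a
threshold grid and verifies that counts change monotonically. Under the
generator's default imaging conditions (below) the test suite measures
recall and precision ≥ 0.95 against ground truth; at substantially
lower SNR the same thresholds trade precision for sensitivity, and
conclusions should be checked across the sweep.

**Epochs and metrics.** Quiet rest is speed < 0.5 cm/s sustained ≥ 1 s
with gaps < 0.2 s absorbed (all three numbers are our choices, exposed
and recorded in output metadata; the defining description is
qualitative — "stationary on the treadmill"). Per-cell metrics report
transients per rest minute (peaks inside rest epochs over total rest
time), mean peak height in both z and dF/F₀ units (the source rule does
not say which; both are kept), and an activity flag (≥ 1 transient
anywhere). Zero rest time flags the rate as undefined rather than
dividing by zero.

## EEG analysis

Preprocessing is a zero-phase 60 Hz notch — realized as a 2nd-order
Butterworth band-stop over 59–61 Hz (Q = 30), since no dedicated IIR
notch is available in the dependency set — followed by a zero-phase
1 Hz 2nd-order high-pass. Spike detection requires a sample to exceed
**both** an absolute 200 µV floor and the causal RMS of the preceding
60 s (conjunctive reading of the rule; "amplitude" is the absolute
deviation of the filtered trace from zero, not peak-to-peak — the
alternative is configurable). Before 60 s of signal exists the RMS
window expands from the record start, and events in that span carry an
`in_rms_warmup` flag. Peaks closer than 50 ms merge into one spike
complex; width is measured at half amplitude.

Trains are greedy left-to-right chains of spikes whose inter-spike
intervals stay within [0.05, 0.6] s; an out-of-band ISI breaks the
chain, and a chain qualifies with ≥ 5 spikes spanning ≥ 3 s. Greedy
chaining on sorted times is equivalent to enumerating maximal ISI-valid
segments, which the test suite verifies against a brute-force oracle.
Classification assigns exactly one label per event: trains overlapping
convulsive/loss-of-balance annotations are seizures, trains without
such overlap are runs of spikes, isolated spikes narrower than 200 ms
overlapping a spasm annotation are myoclonic, and a seizure with a
hindlimb-extension annotation is fatal when the post-event RMS stays
below 25% of the pre-event baseline RMS for ≥ 30 s. The suppression
criterion quantifies a qualitative description ("suppressed EEG
signal"); the pre-event reference is the 30 s before onset (the ictal
RMS itself is dominated by the seizure's spikes) and measurement starts
1 s after the last spike so its own tail is not counted. Behaviour
always arrives as an annotation track; it is never inferred from the
EEG.

## Synthetic data: what it emulates, and what it does not

Every generator is seed-deterministic (bit-identical output for
identical seed, without disturbing the caller's RNG stream) and returns
its generating truth alongside the data.

- `gen_current_clamp` — leaky integrate-and-fire membrane (R = 150 MΩ,
  τ = 15 ms, rest −70 mV, threshold −40 mV by default) with closed-form
  step responses and an inserted piecewise-linear AP template whose
  breakpoints are snapped to the sample grid, so threshold, slopes and
  APD50 have exact analytic truth. The analytic rheobase is
  (V_thr − V_rest)/R. Default acquisition noise is 0 mV: the recovery
  studies judge extractor geometry at one-sample resolution, which
  broadband noise at the derivative level would dominate; a
  `noise_sd_mV` parameter exists for realism studies. Not emulated:
  conductance-based AP shapes, adaptation, channel noise.
- `gen_vclamp_family` — I(V,t) = G_max·B(V)·(V − E_rev)·(1 − e^{−t/τ(V)})
  with a sigmoid τ(V) falling from 7 to 1 ms with depolarization and
  Gaussian current noise scaled as a fraction of the maximal current
  (5% in the recovery studies). Not emulated: inactivation, series-
  resistance error, capacitive transients.
- `gen_paired_recording` — Bernoulli release (default failure
  probability 0.3) with geometric per-pulse depression r^(i−1) (default
  0.7), difference-of-exponentials PSC kernel (rise 0.5 ms, decay
  8 ms), Gaussian latency jitter around 1.2 ms, and current noise. Not
  emulated: stochastic quantal amplitude variation, receptor
  desensitization, asynchronous release.
- `gen_calcium` — per-cell Poisson transients (1.2/min at rest, 3/min
  during locomotion) convolved with an instantaneous-rise, 0.7 s-decay
  kernel — typical of fast genetically encoded indicators — at 0.5
  dF/F₀ amplitude (lognormal, CV 0.2) against 0.02 dF/F₀ frame noise,
  slow sinusoidal drift, per-cell baselines, an alternating 60 s
  rest / 30 s locomotion schedule, and optional global discharges
  (1.0 dF/F₀, 0.3 s decay) added to every cell. The amplitude and noise
  defaults describe bright-indicator imaging at 30 Hz, a peak SNR of
  25; they are the generator's study conditions, not tuning knobs. Not
  emulated: neuropil contamination, motion artifacts, bleaching,
  spike-to-calcium nonlinearity.
- `gen_eeg` — 1/f colored-noise background (spectral shaping of white
  noise, α = 1, 30 µV SD) with inserted asymmetric biphasic
  spike-and-wave templates (sharp Hann spike over the first third of
  the 80 ms width, smaller opposite slow wave; smooth edges so the
  template does not ring through the notch filter), spike trains
  (10 spikes at 0.4 s ISI by default, spanning 3.6 s), isolated
  myoclonic spikes, a matching annotation track, and an optional fatal
  scenario in which the signal collapses to 5% amplitude after the
  final train. Not emulated: sleep architecture, movement artifacts,
  electrode drift.

Passing tests on these generators demonstrate that each pipeline
recovers the quantities it claims from data with the assumed
statistical structure. They do not demonstrate robustness to the
artifacts listed as "not emulated", which real recordings contain; the
QC rules, configurable thresholds and robustness sweeps exist for that
reason.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen to make
Monte-Carlo error comfortably smaller than each stated tolerance:
100 seeded families for Boltzmann recovery, 50 cells at 100 kHz for AP
features, 100 cells × 10 min at 30 Hz for transient scoring, 20 × 1 h
records at 500 Hz for the train detector, 200 sweeps for synaptic
rates, 10⁵ entries for the alternation expectation, and exhaustive
enumeration up to margins of 30 for the exact test. Tolerances follow
the quantities' own error scales (one sample period for APD50, binomial
error for rates, half a grid step against the brute-force Boltzmann
oracle).

Other numerical choices: time is sampling rate plus 0-based sample
index everywhere (no stored time vectors; outputs report seconds from
record start); zero-variance traces return empty event tables rather
than NaN z-scores; ties in peak thinning resolve toward the taller
peak; the EDF reader/writer pair implements the 16-bit standard layout
directly because no installed R package provides one, and the CSV +
YAML sidecar path is fully self-sufficient so no binary fixtures are
needed anywhere in the tests.

## Known limitations

- ABF and HDF5 containers are not read in this build; recordings
  arrive via CSV + YAML (or EDF for EEG).
- The membrane/cytosol ratio assumes isotropic pixels; the distance
  transform is Euclidean on the pixel grid.
- The activation-τ fit assumes a single exponential; strongly sigmoidal
  activation would need a delay term the package deliberately omits.
- Classification trusts the annotation track; contradictory annotations
  are flagged, never resolved silently.
- The transient detector's stated thresholds are permissive by design;
  report results across the robustness sweep when SNR is low.
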