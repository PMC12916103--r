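# pvephys

Quantitative analysis of fast-spiking interneuron physiology in R.

Cortical parvalbumin-positive interneurons (PV-INs) rely on Kv3-family
voltage-gated potassium channels to repolarize quickly enough to fire at
hundreds of Hz. When Kv3.1 function is lost — as in *KCNC1*-related
epileptic encephalopathy — action potentials broaden, firing rates
collapse, inhibition weakens, and seizures emerge. Characterizing that
chain experimentally takes five very different kinds of recording, each
with its own bespoke quantitative pipeline. `pvephys` implements those
pipelines as one tested package, for electrophysiologists and imaging
labs who need reproducible versions of:

- **Current clamp** — spike detection (−10 mV peak floor), single-AP
  waveform features (threshold at 5% of the maximal upstroke, amplitude
  = peak − threshold, APD50 with interpolated half-amplitude crossings,
  AHP as the absolute post-spike minimum), passive properties (median
  resting Vm, input resistance from the −20 pA step), F–I curves from 1 s
  steps between −100 and 500 pA, rheobase as the largest step that did
  *not* evoke spikes, and the −50 mV / 20% access-resistance QC rule.
- **Voltage clamp** — baseline-subtracted peak and steady-state currents
  from 100 ms step families, current density (pA/pF), normalized
  conductance G(V) = I/(V − E_rev), Boltzmann fits
  G/G<sub>max</sub> = 1/(1 + exp(−(V − V<sub>½</sub>)/k)), single-exponential
  activation time constants, and Nernst reversal potentials
  E = (RT/zF)·ln([X]<sub>out</sub>/[X]<sub>in</sub>) assembled from salt
  recipes with full stoichiometry (2 mM MgCl₂ contributes 4 mM Cl⁻).
- **Paired recordings** — unitary IPSC/EPSC amplitudes per presynaptic
  AP (>10 pA or failure), failure rates and amplitude profiles over the
  first five pulses, paired-pulse ratios as ratios of mean amplitudes,
  AP-peak-to-onset latency, and connection probabilities with a
  two-sided Fisher exact test computed by hypergeometric enumeration.
- **Two-photon calcium imaging** — dF/F₀ with a 10th-percentile baseline
  interpolated across 1000-frame blocks, field-of-view discharge
  detection (1 Hz high-pass, z > 5), per-cell transient detection
  (moving-mean smoothing, z ≥ 1, 200 ms minimum separation, prominence
  ≥ 0.5 z) with threshold-robustness sweeps, locomotion epoching, and
  per-cell rest-state activity metrics.
- **EEG** — 60 Hz notch + 1 Hz high-pass preprocessing, epileptiform
  spike detection (>200 µV *and* above the preceding minute's RMS),
  spike-train grouping (≥5 spikes, ISIs 0.05–0.6 s, ≥3 s span), and
  rule-based classification into runs of spikes, seizures, myoclonic
  seizures and fatal seizures with post-ictal suppression.

A first-class synthetic-data module (`gen_current_clamp`,
`gen_vclamp_family`, `gen_paired_recording`, `gen_calcium`, `gen_eeg`)
produces seed-controlled recordings for every modality together with
their generating ground truth, so each detector and fitter is verifiable
without any raw data.

## Worked example

Simulate a fast-spiking cell, extract its AP features and F–I curve:

```r
library(pvephys)

sim   <- gen_current_clamp(seed = 1, sampling_rate_hz = 1e5,
                           steps_pA = seq(-100, 500, 100))
v     <- sim$ramp$sweeps[[1]]                 # 100 pA/s depolarizing ramp
peaks <- detect_spikes(v, 1e5)
ap_features(v, 1e5, peaks[1])
#>   spike_time_s threshold_mV peak_mV amplitude_mV upstroke_mV_ms
#> 1        2.015          -40      12           52        247.619
#>   downstroke_mV_ms apd50_ms ahp_mV
#> 1          -88.172      0.4    -70

fi <- fi_curve(sim$steps)
rheobase(fi)$rheobase_pA
#> [1] 200
```

The extracted threshold (−40 mV), amplitude (52 mV) and APD50 (0.40 ms)
equal the generator's template truth, and the rheobase matches the
cell's analytic value (30 mV threshold depolarization / 150 MΩ =
200 pA). The same pattern holds in voltage clamp:

```r
fam <- gen_vclamp_family(seed = 2, vhalf_mV = -5, k_mV = 8)
gv  <- conductance_curve(steady_state_current(fam$family),
                         fam$family$steps_mV, fam$truth$e_rev_mV)
fit_boltzmann(gv$g_norm, gv$step_mV)
#> <boltzmann_fit> Vhalf = -4.98 mV, k = 7.87 mV, Gmax = 0.999, RMS = 0.0079

sol <- macropatch_solutions()
nernst_potential(sol$internal, sol$external, "K", +1)
#> [1] -105.1471   # mV, at 32 C
```

A thin command-line front end over the same functions lives at
`inst/cli/pvephys.R` (subcommands `simulate`, `ephys`, `vclamp`,
`pairs`, `calcium`, `eeg`, each driven by a YAML config).

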