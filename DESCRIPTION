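Package: pvephys
Title: Analysis of Fast-Spiking Interneuron Electrophysiology, Calcium
    Imaging, and EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cellular neurophysiology recordings
    from studies of fast-spiking, parvalbumin-positive cortical
    interneurons: action-potential waveform feature extraction and
    firing-rate curves from current-clamp sweeps, Boltzmann
    conductance-voltage analysis of voltage-gated potassium currents from
    voltage-clamp step families, unitary synaptic current measurement from
    paired recordings (failure rates, paired-pulse ratios, latencies,
    connection statistics), two-photon calcium transient and
    hypersynchronous-discharge detection with percentile-interpolated
    dF/F0 baselines, rule-based EEG epileptiform spike, spike-train and
    seizure classification, and small auxiliary metrics
    (membrane/cytosol immunofluorescence ratio, Y-maze spontaneous
    alternation). A seed-controlled synthetic-data module generates
    ground-truth recordings for every modality so each analysis stage is
    verifiable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    minpack.lm,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
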