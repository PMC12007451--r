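Package: ictalysis
Title: Interictal Discharge and Hippocampo-Cortical Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic multi-site local field potential
    recordings and operant behavior in rodent models of temporal lobe
    epilepsy. Detects interictal discharges with a z-scored squared-signal
    statistic, summarizes their density, amplitude and duration, computes
    multitaper power spectra and coherence, Morlet spectrograms,
    phase-amplitude coupling via the normalized-entropy modulation index,
    frequency-domain (Geweke) Granger causality from bivariate
    autoregressive fits, peri-event sliding-sweeps cross-correlograms,
    discharge-triggered locomotion averages, and probabilistic
    reversal-task metrics with bootstrap slope comparison. Includes a
    calibrated synthetic-data generator that emulates the statistical
    structure of such recordings so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
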