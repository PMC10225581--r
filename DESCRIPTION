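Package: meaburst
Title: Spike Detection and Synchronized-Burst Analysis for Multielectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro multielectrode array (MEA)
    electrophysiology: Butterworth band-pass filtering of raw extracellular
    voltage, adaptive spike detection at -5.5 x sigma with a median-absolute-
    deviation noise estimate, array-wide spike detection rate (ASDR)
    histograms, envelope-based synchronized-burst detection with electrode
    participation criteria, per-well network metrics, and a group-comparison
    layer (ROUT outlier removal at a chosen false-discovery rate, one-way
    ANOVA with mean and SEM reporting, and 2^-ddCt qPCR fold changes).
    Includes a seeded synthetic-recording generator (Poisson background
    firing, periodic network bursts with partial electrode participation,
    biphasic spike waveforms, Gaussian noise) that retains full ground truth
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
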