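Package: dualtaskr
Title: Simulation and Analysis of Dual-Task Working-Memory Interference
    with EEG and Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze dual-task experiments in which
    participants hold auditory or visual sequences (temporal or spatial
    features) in working memory while performing an intervening auditory
    judgment. Provides a synthetic experiment generator (blocked condition
    designs, stimulus sequences, a logistic behavioral observer, pupil
    traces with blinks, and EEG with stimulus-locked potentials and
    alpha-band oscillations), a pupillometry cleaning pipeline (blink
    detection, interpolation, trial rejection, z-scoring), paired
    permutation tests for time series with run-length and windowed
    percentile criteria, an event-related potential pipeline with
    peak-to-peak artifact rejection and a three-way repeated-measures
    ANOVA on P2 amplitudes, Morlet wavelet time-frequency analysis with
    individual alpha frequency estimation, and logistic mixed-effects
    behavioral models with baseline-cycling post-hoc contrasts under
    Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
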