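Package: qdetect
Title: Quickest Detection of Seizure Onset from Multichannel Cross-Power Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Online seizure-onset detection for multichannel intracranial EEG.
    Computes sliding-window band-limited cross-power connectivity matrices and
    tracks the largest singular value of the brain network as a one-dimensional
    detection statistic. Fits a two-state (nonictal/ictal) hidden Markov model
    with history-dependent Poisson generalized-linear-model emissions, filters
    the Bayesian a-posteriori probability of the ictal state online, and
    synthesizes an optimal stopping (quickest detection) policy by dynamic
    programming over the information state, yielding a stage-adaptive detection
    threshold that trades detection delay against false positives. Includes a
    Bayesian-estimator and a heuristic-threshold baseline, an event-scoring
    protocol with a 20-second matching tolerance, a gamma sensitivity sweep,
    and a synthetic multichannel data generator so the whole pipeline is
    exercisable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
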