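Package: msbridge
Title: Brain State-Transition Cost from EEG Microstates via Schrodinger Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the cost of moving the brain between conditions from
    multichannel EEG. Extracts EEG microstates with a polarity-invariant
    modified k-means on global-field-power peak topographies, selects the
    number of states by a cross-validation criterion, back-fits templates to
    continuous recordings, estimates per-condition microstate coverage
    distributions and the resting two-step joint transition matrix, and
    computes the Schrodinger-bridge (entropy-regularized optimal transport)
    transition cost between the resting and each task distribution with a
    Sinkhorn solver. Includes a synthetic-cohort generator with known
    topographies and metastable Markov label dynamics, group-level
    statistics (coverage tests against chance, Benjamini-Hochberg FDR,
    condition design coding, Stroop-effect contrasts), and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
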