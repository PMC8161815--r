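Package: hypnomatch
Title: Validation of Wearable Sleep-Tracker Hypnograms Against Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to validate sleep-stage scoring from wearable sleep
    trackers against polysomnography (PSG) ground truth. Provides
    epoch-indexed hypnogram input/output and clock-time synchronization,
    AASM-based categorization of PSG stages to the coarser alphabets
    reported by consumer devices, extraction of wake-sleep and
    sleep-architecture features (total sleep time, sleep efficiency,
    wakefulness after sleep onset, stage percentages), a localized mismatch
    index (LMI) that scores sleep-stage-transition agreement chronologically
    epoch by epoch, Fleiss' kappa interrater gating, per-stage confusion
    metrics, paired feature-comparison tests, and a Markov-chain hypnogram
    simulator with a controllable device-error channel for closed-loop
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
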