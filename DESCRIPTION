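Package: lgdint
Title: Local-by-Global Auditory Novelty Interactions in Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for local-by-global (L x G) auditory novelty
    interactions in intracranial EEG recorded during a local/global deviant
    (LGD) vowel-quintuple paradigm. Builds the stimulus schedule, extracts
    high-gamma (70-150 Hz) power envelopes from continuous recordings,
    computes the 2x2 factorial interaction contrast
    (LDGD - LSGD) - (LDGS - LSGS), assesses per-site significance with a
    cluster-based permutation test, classifies sites by interaction sign,
    aggregates prevalence and onset latency by cortical region of interest
    and arousal state, and scores target-detection behavior (hit rate,
    d-prime, reaction time) with the matching nonparametric group tests.
    A synthetic-data module generates continuous recordings and button
    presses with known injected effects so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
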