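Package: riftkin
Title: RNA Decay Kinetics from Rifampicin Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates genome-wide RNA half-lives and decay rates from
    rifampicin transcription-arrest time courses. Implements the twofold
    decay-step half-life estimator and a relative two-phase exponential decay
    model with grid breakpoint selection and a delayed-onset rule, plus
    downstream analyses: operon position-stability correlation and decay
    profile typing (plateau versus transient-rise polycistronic profiles),
    probe-level sub-gene fits with RNA polymerase elongation-rate estimation
    (v = s/t), fuzzy c-means clustering of standardized decay profiles with
    hypergeometric functional enrichment, delta-delta-Ct qPCR quantification
    and array-versus-qPCR concordance scoring. Includes a seeded synthetic
    chase-data generator with known kinetic ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ggplot2,
    optparse
Config/testthat/edition: 3
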