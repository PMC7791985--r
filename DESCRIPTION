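Package: metorgan
Title: Organ-Specific Metastasis Signatures from Rank-Based Differential
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies organ-specific metastasis gene signatures by
    integrating heterogeneous microarray datasets and detecting
    differential expression from within-sample relative expression
    orderings (stable gene pairs, per-sample Fisher reversal tests, and a
    subpopulation-level binomial test), followed by a heteroscedastic
    standardized effect-size screen, directional intersection of
    per-origin gene lists with hypergeometric overlap statistics,
    up/down-stratified pathway enrichment, and survival-based validation
    with univariate Cox screening, risk indices, and log-rank tests.
    Includes a synthetic-data generator emulating multi-platform,
    batch-affected cohorts so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
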