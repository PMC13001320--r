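Package: circage
Title: Circadian Rhythm Detection and Clock-Senescence Uncoupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing circadian dysregulation in aging
    transcriptomes. Implements per-gene cosinor regression with simulated
    quantile-residual diagnostics and circadian classification, relational
    clock-gene metrics (above-mean phase windows, pairwise coupling with age
    contrasts), epsilon-band stratification of single cells on a two-gene
    clock-senescence axis with rank-sum differential expression, differential
    variability via the Brown-Forsythe statistic, and amplitude-weighted
    circular phase-set enrichment with Rayleigh tests and signed circular
    phase shifts between age groups. A seeded synthetic-data generator
    emulates four-timepoint bulk time courses, fibroblast-style phase tables
    and three-population two-gene single-cell mixtures for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
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
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
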