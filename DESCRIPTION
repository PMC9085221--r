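Package: dgsmeta
Title: Decisive Gene Strategy: Trial Sequential Analysis for Candidate-Gene Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cumulative random-effects meta-analysis of candidate-gene
    case-control studies with trial sequential analysis (TSA). Pools
    allele-model odds ratios per locus and ethnicity with the
    DerSimonian-Laird estimator, computes the diversity-adjusted required
    information size, derives O'Brien-Fleming-type monitoring and futility
    boundaries by Lan-DeMets alpha/beta spending with recursive numerical
    integration, and classifies each locus as a conclusive risk factor,
    conclusive protective factor, conclusively unassociated, or in need of
    a stated number of additional samples. Includes a Hardy-Weinberg
    study-stream simulator for type-I-error and power evaluation of the
    whole sequential procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
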