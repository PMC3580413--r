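Package: gxescreen
Title: Two-Stage Screening for SNP by Treatment Interactions in
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage procedure for detecting SNP by
    treatment interactions in randomized controlled trials nested in a
    matched case-control sample: a first-stage marginal per-SNP screen
    with genotype principal-component adjustment, a second-stage
    case-only offset-logistic interaction test combined across two
    independent trial components into a two-degree-of-freedom
    chi-square statistic with Benjamini-Hochberg false discovery rate
    control, genotype-stratified intervention odds ratios, and
    AUC-based assessment of incremental discrimination.  Includes a
    synthetic cohort generator (population structure via
    Balding-Nichols allele-frequency drift, linkage-disequilibrium SNP
    pairs, randomized trial components, logistic outcome models and
    one-to-one matched control selection) so the full pipeline is
    testable without access to individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
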