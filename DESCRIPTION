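Package: c4coopt
Title: Gene Co-Option Bias Analysis for C4 Photosynthesis Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether gene lineages were preferentially co-opted
    for C4 photosynthesis according to their ancestral transcript abundance.
    Implements rpkm quantification from read-count tables, threshold-based
    co-option calling per independent C4 origin with a non-C4 exclusion
    filter, a resampling test for co-option bias conditioned on gene-family
    sizes, maximum-likelihood Brownian-motion ancestral-state reconstruction
    of expression traits with confidence intervals, sequential-ANOVA linear
    modelling of co-option counts, and a synthetic-data generator that makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
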