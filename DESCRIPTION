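Package: propbench
Title: Benchmarking Chemosensory Phenotyping Strategies for GWAS on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates staircase and labelled-magnitude-scale (gLMS) phenotyping of a
    bitter-taste trait driven by a single strong receptor locus, runs a from-scratch
    quantitative-trait GWAS (allele-dosage linear regression with ancestry principal
    components, covariate residualisation, Hardy-Weinberg/MAF/call-rate QC and genomic
    control) under every phenotype representation commonly used for threshold data, and
    provides analytic power-to-detect calculators plus scripted experiments comparing
    representations, panel-size trade-offs, binary-cutoff scans and conditional
    re-analysis on fully synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
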