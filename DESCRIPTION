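Package: mipmeter
Title: Pooled Strain-Frequency Estimation and Fitness Traits from
    Molecular Inversion Probe Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design strain-unique molecular inversion probe (MIP) panels
    from a multi-sample VCF, count SNV alleles from targeted single-end
    sequencing reads, quality-control probes against an equimolar pilot,
    estimate strain frequencies in pooled competition experiments, and
    derive starvation-resistance trait metrics (zero-intercept Slope and
    PC1) for quantitative genetic mapping. Includes hypergeometric
    enrichment with Bonferroni correction, hyper-divergent region
    classification, logistic starvation-survival fitting with half-life
    comparison and power analysis, and a seeded pooled-competition
    simulator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    vcfR,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
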