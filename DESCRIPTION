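Package: methdrift
Title: Multi-Level DNA Methylation Analysis of Case/Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-level analysis of Illumina-style
    DNA methylation beta-value matrices in case/control designs: per-probe
    epigenome-wide association (EWAS) with covariate adjustment and
    multiple-testing control, cross-study meta-analysis (sample-size
    weighted Z and DerSimonian-Laird random effects with heterogeneity
    statistics), application of user-supplied epigenetic clocks and age
    acceleration, stochastic epigenetic mutation (SEM) calling from
    control-derived interquartile reference ranges with logistic drift
    burden modelling, sliding-window cumulative-hypergeometric detection
    of SEM-enriched regions (epivariations), and heuristic gene
    prioritization. Includes a synthetic cohort generator with recorded
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
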