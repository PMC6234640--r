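Package: ascertainr
Title: GWAS Ascertainment Bias Simulation and Ancestry-Aware Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genome-wide association study (GWAS)
    ascertainment -- study-cohort ancestry, genotyping platform, sample
    size, and effect-size model -- biases risk-allele frequencies across
    continental populations, and to correct genetic risk scores using
    ancestral/derived allele states. Provides a multi-population
    allele-frequency panel data model with VCF import and array subsetting,
    a hierarchical Balding-Nichols synthetic-panel generator emulating
    out-of-Africa bottleneck drift and small-panel array ascertainment, an
    analytic case-control power calculator with a Monte-Carlo oracle,
    rejection-sampling simulation of GWAS locus discovery, empirical
    frequency-difference statistics, and raw, standardized, and corrected
    genetic risk scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
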