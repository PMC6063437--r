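Package: uralens
Title: Uracil Lesion Density and Mutation-Rate Estimation for Yeast Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of uracil accumulation and uracil-driven
    mutagenesis in yeast genomic DNA. Converts long-amplicon qPCR amplification
    loss after uracil-DNA-glycosylase/Endonuclease-VIII treatment into lesion
    densities (uracils per 10 kb) via the Poisson zero-class equation, with
    bootstrap confidence intervals and unpaired t-test group comparisons.
    Estimates mutation rates from Luria-Delbruck fluctuation assays by the
    Lea-Coulson method of the median, maximum likelihood on the
    Ma-Sandri-Sarkar distribution, and the p0 method; computes median mutation
    frequencies with order-statistic confidence intervals. Partitions overall
    rates into base-substitution classes with Wilson intervals and fold-change
    comparisons. Includes seeded generators for Luria-Delbruck mutant counts,
    qPCR plates and mutation spectra so every stage is testable end to end.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
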