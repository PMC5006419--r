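Package: rarebin
Title: Biologically Informed Binning and Burden Testing of Rare Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Collapses low-frequency sequence variants from VCF files into
    gene, pathway, and intergenic bins defined by plain-text knowledge files
    (regions and grouped region sets), with configurable non-major allele
    frequency thresholds, additive/dominant/recessive genotype encodings, and
    Madsen-Browning style variant weighting computed from a choice of sample
    strata (controls only, cases/controls minimum or maximum, or the overall
    population).  Provides logistic-regression and Wilcoxon rank-sum burden
    tests on the per-sample bin scores, and a seeded simulation harness that
    estimates type I error and power of the weighting schemes under
    case-control designs with a prevalence-calibrated logistic disease model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
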