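Package: tmzmut
Title: Dropout Screens and Mutational-Signature Analysis of Temozolomide
    Resistance
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for studying how glioblastoma cells tolerate
    and mutate under temozolomide (TMZ). Implements gene- and pathway-level
    dropout statistics for pooled CRISPR knockout screens of DNA-damage
    response (DDR) genes (counts-per-million normalisation, per-guide log2
    PD20/PD0 ratios, the SigmaFC gene score with an empirical permutation null
    built from non-targeting control sgRNAs, a combined pathway Z-test and a
    paired-t pathway dropout statistic); somatic variant filtering and
    construction of per-clone 6-class and 96-trinucleotide-context mutation
    catalogs with signature refitting by non-negative least squares and
    Signature-11-based hypermutation calling; and a proliferation-adjusted
    logistic model relating RAD18 expression and MGMT status to hypermutation
    in patient cohorts. Ships synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
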