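Package: tohscan
Title: Tracts of Homozygosity: Detection, Case-Control Association and
    Exome Feature Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls per-individual tracts of homozygosity (TOH) from SNP
    array genotypes, builds common-TOH (cTOH) regions shared by a minimum
    number of subjects, and tests each region for case-control association
    with a logistic model adjusted for sex and genotype principal
    components (Wald tests, Benjamini-Hochberg FDR).  Significant regions
    are then integrated with repeat-element annotations and per-sample
    insertion/deletion calls to shortlist candidate genes using a
    cross-sample recurrence rule.  Includes genotype quality control with
    an exact Hardy-Weinberg test, an EigenStrat-style PCA for population
    stratification, PLINK/BED/minimal-VCF readers and writers, and a
    synthetic-cohort simulator with planted homozygous tracts and exome
    annotations so the whole pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
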