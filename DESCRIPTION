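Package: rohsurv
Title: Runs of Homozygosity, Inbreeding and Case-Only Survival Association
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Case-only analysis of genomic homozygosity and survival outcome
    from SNP array genotypes. Implements per-SNP homozygote/heterozygote
    association with Benjamini-Hochberg false discovery rate control, a
    sliding-window caller for runs of homozygosity (ROH) with the chance-run
    minimum-length derivation, pooling of overlapping ROHs into consensus
    regions with carrier association tests, ROH burden and genomic inbreeding
    coefficients (variance-of-additive-values, excess-homozygosity and
    uniting-gametes estimators, and F_ROH), selection-scan statistics
    (Tajima's D, Fay-Wu's H, EHH and iHS) computed from phased haplotype
    panels, and a synthetic-cohort generator with Balding-Nichols population
    structure for end-to-end validation. Genotypes travel as a
    SummarizedExperiment-derived container; segments and regions as GRanges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SNP, GenomeWideAssociation, StatisticalMethod, Survival
RoxygenNote: 7.3.3
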