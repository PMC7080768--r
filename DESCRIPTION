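Package: isopop
Title: Population Genomics of Isolated Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising genetically isolated
    population cohorts from whole-genome sequencing data. Implements
    reference-imputation-panel site selection (allele-count and depth
    rules with singleton rescue across cohorts and external resources),
    imputation quality metrics (IMPUTE-type info score, genotype
    concordance r2 by minor allele frequency), association-study variant
    QC and direction-consistent sample-size-weighted meta-analysis,
    population-structure statistics (LD pruning, PCA, Weir-Cockerham
    Fst, runs of homozygosity, inbreeding coefficients), extended
    haplotype homozygosity and iHS selection scans with gene-level
    candidate calling, drifted deleterious-variant enrichment (DVxy)
    with bootstrap uncertainty, and putative human-knockout detection
    with TOTAL/PARTIAL classification and gene-intolerance comparison.
    Ships a founder-mosaic cohort simulator so every stage is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
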