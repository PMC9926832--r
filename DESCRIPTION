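Package: ulcgwas
Title: Genotype Imputation and Association Testing for Ultra-Low-Coverage
    Whole-Genome Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for ultra-low-coverage (below 0.1x) whole-genome
    sequencing of large cohorts: pooled-read maximum-likelihood SNV discovery
    with a likelihood-ratio test, hidden-Markov-model genotype imputation with
    K ancestral haplotypes (diploid Li-and-Stephens copying model, EM-fitted),
    IMPUTE2-style INFO scores, exact Hardy-Weinberg filtering, score-test
    association of a quantitative trait on genotype dosages with principal
    component and clinical covariates, LD-based definition of genomic risk
    loci, and a coverage-by-sample-size benchmarking harness. Includes a
    synthetic-cohort generator (haplotype panels with tunable linkage
    disequilibrium, sibling families, batch structure, and read pileups) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
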