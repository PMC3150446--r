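Package: transqtl
Title: Cis- and Trans-eQTL Discovery with Permutation FDR, Confounder
    Correction, and Artifact Falsification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping cis- and trans-acting expression quantitative
    trait loci (eQTLs) in two-platform microarray cohorts: genotype quality
    control (exact Hardy-Weinberg test, minor allele frequency, call rate),
    quantile normalization to the median distribution, principal-component
    confounder removal with protection of genetically controlled components,
    Spearman rank association with square-root-sample-size weighted Z
    meta-analysis, permutation-based false-discovery-rate control, probe
    primer-polymorphism and cross-hybridization artifact filters,
    permutation plus generalized-extreme-value enrichment testing,
    unlinked-SNP-pair convergence statistics, co-expression thresholding and
    phenotypic-buffering summaries, and a synthetic-data generator that
    plants known effects with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    data.table,
    jsonlite,
    yaml,
    matrixStats,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
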