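Package: DNMburden
Title: De Novo Mutation Burden and Noncoding Enrichment Testing in Trio Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects de novo mutations (DNMs) in parent-offspring trio VCFs,
    annotates them against gene models, and tests genes for enrichment of
    coding and noncoding DNMs. Implements a case-only Poisson test with
    gene-specific expected counts (coding, missense, likely-gene-disrupting,
    and CADD>=15 noncoding via a noncoding/coding length ratio), a
    segment-based case-only test on 1 kb windows with constraint-derived
    background mutation rates, case-control carrier burden statistics
    (fold change, one-sided Fisher exact test, Haldane-Anscombe corrected
    odds ratios), Fisher combination across variant classes and cohorts,
    and Bonferroni/Benjamini-Hochberg correction. A fully self-contained
    synthetic-cohort generator produces reference sequences, gene models,
    mutation-rate tables, per-site score tracks, 1 kb background bins and
    per-family trio VCFs with planted DNMs and filter-violating decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantDetection, GeneticVariability, StatisticalMethod
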