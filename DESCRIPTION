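Package: katascan
Title: Kataegis Detection and Cohort-Level Analysis of Somatic SBS Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects kataegis loci (localized somatic hypermutation) in
    per-sample single base substitution (SBS) catalogs by the
    intermutation-distance run rule, characterizes detected loci
    (pyrimidine-normalized substitution spectra, locus sizes, per-chromosome
    counts, and recurrence in fixed-width genome bins), quantifies enrichment
    of kataegis-associated SBSs in genomic annotation tracks, and provides
    the cohort-level association statistics typically used alongside such
    analyses (rank-based two- and k-group tests, chi-square driver
    association with Benjamini-Hochberg adjustment, tumor mutational burden,
    and single-sample metagene rank scores). A seeded synthetic-cohort
    generator with known ground truth supports end-to-end validation of
    every stage without access to controlled-access tumor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
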