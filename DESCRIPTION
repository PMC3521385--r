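Package: mitocount
Title: Mitochondrial DNA Copy Number Estimation from Whole-Genome
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Mitocount", "Developers", email = "mitocount@example.org",
           role = c("aut", "cre"))
Description: Estimates the average mitochondrial DNA (mtDNA) copy number per
    diploid cell from paired-end whole-genome sequencing (WGS) reads. The
    assay proceeds in three stages: guided greedy-overlap assembly of the
    sample's homoplasmic circular mtDNA consensus against a reference
    mitochondrial genome; error-tolerant separation of mitochondrial read
    pairs from the bulk WGS stream using a k-mer seed index with full-read
    verification and paired-end insert-distance validation; and conversion
    of per-run mitochondrial base fractions into a copy-number estimate
    k = mtBases * 2N / ((allBases - mtBases) * M), with one-way ANOVA for
    comparing per-run ratios across sample groups. A paired-end read
    simulator with truth labels supports end-to-end validation, and a small
    command-line interface binds the stages into a pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
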