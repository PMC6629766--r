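Package: locuskit
Title: Targeted Long-Read Analysis of a Single Gene Locus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for targeted long-read sequencing of a
    single gene locus, exercised end-to-end on a synthetic diploid locus
    simulator with complete ground truth. Implements PCR-duplicate marking by
    alignment endpoints, diploid pileup genotyping with a phase-consistency
    filter, read-backed phasing with phase-block statistics, haplotyping of
    short tandem repeats and low-complexity regions by size/similarity
    clustering and per-cluster consensus, collapse of full-length cDNA reads
    into isoforms with canonical-splice and full-length-support filtering,
    splice-pattern classification and abundance tables, short-read junction
    validation, ORF prediction, and isoform-level SNP calling with a Fisher
    exact test, Bonferroni correction, homopolymer exclusion and per-sample
    read-count genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    IRanges,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
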