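Package: flanklift
Title: Flanking-Sequence Liftover of SNP Array Markers Between Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Flanklift", "Developers", email = "maintainer@flanklift.org",
           role = c("aut", "cre"))
Description: Maps SNP-array markers from one genome assembly version to
    another using the markers' flanking sequences: a k-mer seeded,
    banded local aligner locates each 101 bp flank query in the target
    assembly, collinear chains built from accepted alignments rescue
    markers without their own acceptable hit, and a validation cascade
    (multi-mapping, allele divergence, strand-aware 100% flank identity)
    classifies every marker's fate. Includes positional annotation
    (genic/near-genic/intergenic), transposable-element and low-identity
    failure-cause classification, minor-allele-frequency spectrum
    statistics across accession collections, a seeded synthetic
    genome-pair simulator with planted truth fates, summary reporting,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
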