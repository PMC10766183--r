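Package: odira
Title: Foldback Junction Discovery and Mechanistic Models of
    Origin-Dependent Inverted Repeat Amplification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying inverted (foldback) copy-number variants of
    the kind that arise by template switching between the leading and lagging
    strands at replication forks (ODIRA). Provides a synthetic-data generator
    that plants interrupted inverted repeats in chromosome-end contigs and
    builds the resulting extrachromosomal and chromosomal products (inverted
    linears, inverted dimeric circles, interstitial triplications); a
    split-read caller that detects, classifies and characterizes foldback
    junctions from 150 bp reads (arm length, spacer, loop side, fragment-level
    support); an exhaustive interrupted-inverted-repeat scanner; a forward
    model of the array-CGH "waterfall" signature produced by snap-back of
    palindromic fragments during labeling; a replication-fork model of which
    repeat spacings and fork directions can produce junctions given the
    lagging-strand Okazaki gap; and the statistical layer comparing used
    versus potential repeats across simulated subclonal populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
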