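Package: mirduet
Title: miRNA Discovery and Two-Library Differential Expression for Plant
    Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for plant small RNA sequencing
    studies that compare two pooled libraries (e.g. a control and a
    stressed sample). Covers adapter and length cleaning of raw reads,
    collapsing to unique tags, perfect-match reference mapping,
    non-coding RNA exclusion, mismatch-tolerant known-miRNA annotation,
    novel miRNA calling from hairpin precursors folded with an internal
    minimum-free-energy dynamic program, reads-per-million
    normalization with pseudocount substitution, the Audic-Claverie
    exact test for two-library count data, Allen-style miRNA target
    expectation scoring with Schwab filters, and 2^-ddCt relative
    quantification of qPCR cycle-threshold tables. Includes a seeded
    synthetic-data generator that plants known miRNA loci, hairpin
    precursors and differential expression for parameter-recovery
    testing, and bundles the published count tables of a radish
    chromium(VI) stress root study as worked-example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
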