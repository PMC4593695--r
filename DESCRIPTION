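Package: concordia
Title: Cross-Platform Concordance of Microarray and RNA-Seq Transcript Abundance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing agreement between transcript-abundance
    measurements from two-channel DNA microarrays and RNA sequencing, with
    qRT-PCR arbitration. Implements cross-channel (fluorophore crosstalk)
    correction and within-array MA-LOWESS normalization for two-colour
    arrays, RPKM normalization with a pseudocount for RNA-seq feature
    probes, a sequence- and Ensembl-ID-based mapping of array probes to
    transcript feature probes, a three-measure correlation suite with
    Fisher's z comparison, a permutation test for the overlap of top-k
    fold-change lists (with an exact hypergeometric oracle), delta-delta-CT
    relative quantification against multiple normalizer genes, and a
    synthetic-data generator emulating a proliferative/quiescent fibroblast
    two-platform study design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
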