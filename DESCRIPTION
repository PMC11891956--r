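Package: litmotu
Title: MOTU Clustering and Large-Scale Integrative Taxonomy for DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational stages of high-throughput integrative
    taxonomy of "dark" (hyperdiverse, mostly undescribed) arthropod taxa from
    COI minibarcodes. Computes uncorrected p-distance matrices with pairwise
    deletion, clusters barcodes into molecular operational taxonomic units
    (MOTUs) by single-linkage objective clustering at one or more distance
    thresholds, classifies MOTUs as singleton/stable/instable across a
    threshold grid and derives the specimen-examination plan of large-scale
    integrative taxonomy (LIT), integrates morphospecies labels via the match
    ratio with split/fuse conflict resolution, and assesses faunal
    completeness between specimen batches with a randomization null. Includes
    a seeded synthetic barcode-community simulator with known species truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
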