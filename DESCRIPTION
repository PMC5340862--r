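Package: consortiumcoupling
Title: Species-Resolved Transcriptomics and Steady-State Physiology of a
    Phototroph-Heterotroph Consortium
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for binary cyanobacterium-heterotroph
    turbidostat experiments run across irradiance- and oxygen-controlled
    steady states. Converts two-species RNA-seq count matrices to
    length-normalized expression (median-of-ratios size factors followed by
    per-kilobase scaling), applies zero-count, low-abundance and low-variance
    gene filters, calls treatment-responsive genes by a two-fold extreme-
    condition rule, co-clusters both species' expression profiles with
    correlation-distance K-means around eigen-gene centroids, and scores
    functional-category enrichment with the hypergeometric exact test.
    Companion physiology tools detect turbidostat steady states, derive
    specific growth rates on a carbon-mole basis, net oxygen production
    rates, photosynthetic quotients and oxygen-sensitivity coefficients, and
    summarize flow-cytometry community composition and background-corrected
    reactive-oxygen-species plate assays. Seeded generators produce every
    input the pipeline consumes, with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    withr,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
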