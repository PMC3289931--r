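Package: sagesig
Title: Comparative SAGE Transcriptomics and Multifunctional Gene Signatures
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative transcriptome analysis of Serial Analysis
    of Gene Expression (SAGE) libraries: ditag extraction from concatemer
    reads, tag counting and tag-to-gene aggregation, library normalization
    to a fixed tag total, construction of a virtual reference library by
    per-tag averaging, pairwise differential expression by two-proportion
    z-tests, derivation of multifunctional gene signatures from overlapping
    functional categories, Monte-Carlo resampling enrichment tests with an
    exact binomial comparison, hierarchical correlation clustering of
    libraries, and efficiency-corrected (Pfaffl) relative quantification of
    validation qPCR data. A synthetic-data module generates complete
    pipeline inputs with a ground-truth ledger for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
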