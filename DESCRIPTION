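Package: metabosig
Title: Metabolite Signature Extraction by Nonnegative Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unsupervised extraction of metabolic signatures from
    nonnegative metabolite-abundance matrices. Implements
    multiplicative-update nonnegative matrix factorization with a
    unit-column-sum signature convention, consensus-based selection of the
    number of signatures via the cophenetic correlation coefficient,
    hierarchical clustering of samples by their signature make-up,
    hypergeometric pathway overrepresentation analysis of signature
    metabolites, and per-metabolite two-group differential statistics with
    fold changes. Includes a synthetic-study generator with planted
    signatures, group-linked signature dominance, multiplicative noise and
    planted fold changes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
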