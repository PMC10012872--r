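Package: ceRNAfly
Title: Age-Related ceRNA Network Inference from Fly Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers competing endogenous RNA (ceRNA) networks between two
    ages of adult Drosophila from circRNA, lncRNA, miRNA and mRNA expression.
    Provides negative-binomial exact-test differential expression with
    median-of-ratios normalization and Benjamini-Hochberg adjustment,
    miRanda-style miRNA binding-site prediction (seed classes, wobble-tolerant
    hybrid alignment, nearest-neighbor duplex free energy), construction of
    sponge/miRNA/mRNA triples with the ceRNA sign-consistency filter,
    hypergeometric GO enrichment of network targets, and qPCR relative
    quantification with RNA-seq concordance calls. A synthetic-data generator
    emulating the two-age study design (planted fold changes and planted
    binding sites with exported ground truth) supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
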