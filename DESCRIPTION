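Package: seqlda
Title: Latent Dirichlet Allocation Topic Models for Nucleotide Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits latent Dirichlet allocation (LDA) mixture models to
    nucleotide sequences represented as k-mer count matrices. Supports three
    featurizations (bulk k-mers, positional k-mers anchored at an alignment
    point such as a splice site, and reading-frame-tagged k-mers), pooling of
    sequences into larger samples, variational Bayes model fitting with a
    deterministic seed, Kullback-Leibler selection of the driving k-mers that
    characterize each topic, likelihood scoring of sequences against topics,
    a topic-to-label score classifier used for intron subtype and reading
    frame prediction (including frame-shift detection), small-ORF scanning
    with coding-potential scoring, and position-wise motif signal curves for
    branch-site and polypyrimidine-tract analysis. A synthetic-sequence
    generator provides topic-structured corpora, anchored intron-like
    sequences with planted motifs, and codon-biased coding sequences so the
    whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
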