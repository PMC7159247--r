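Package: repliclass
Title: Length-Binned Sequence Composition Classification of Plasmid and
    Chromosomal Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies nucleotide sequences (assembled contigs or reference
    replicons) as plasmid or chromosomal in origin from their canonical k-mer
    composition. Sequences are represented by canonical 3-7-mer frequency
    vectors (10952 features) and scored by one of four logistic regression
    models, each trained on reference fragments of a fixed length (1 kb,
    10 kb, 100 kb, 500 kb); a query is routed to the model of nearest
    training length. Includes fragment samplers for training and held-out
    evaluation, count-based precision/recall/F1 reporting with length
    stratification, precision-recall curves, and a synthetic-data module
    that builds compositionally distinct reference sets and simulated
    communities (log-normal genome abundance, geometric plasmid copy
    number) so the full pipeline runs without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    glmnet,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
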