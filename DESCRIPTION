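Package: rankvar
Title: Phenotype-Driven Ranking of Genes and Variants from VCF Files
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for prioritizing candidate Mendelian disease
    genes and variants from VCF files. Variants are joined with functional
    annotations, passed through configurable filtration (variant type,
    zygosity, trio inheritance, splice-region distance and z-score, predictor
    scores, population allele frequency, ClinVar class, OMIM and gene-panel
    membership), and scored by a small neural network trained on rank-decay
    labels derived from reference gene prioritizers. Phenotype evidence enters
    through Resnik-style semantic similarity between patient HPO terms and
    gene-associated disease terms, directly and via the protein interactome.
    A mutation-disease literature knowledge base supplies evidence sentences
    and popularity ordering; a fault-tolerant FIFO task-queue scheduler,
    a synthetic-cohort generator and a top-k evaluation harness make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    nnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
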