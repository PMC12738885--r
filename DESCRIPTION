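Package: degbrin
Title: Brain-Region DEG Co-Occurrence Networks and Interpretable Graph
    Convolutional Classification of Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-region transcriptomic case-control studies of
    neurodegenerative disease. Implements per-region linear-model
    differential expression with empirical-Bayes variance moderation and
    Benjamini-Hochberg control, hypergeometric gene-set enrichment, the
    construction of a brain-region interaction network (DEG-BRIN) whose
    edge weights count differentially expressed genes shared between
    regions, tiered protein-protein interaction hub analysis by degree and
    betweenness centrality, and an interpretable two-layer graph
    convolutional classifier with trainable gene and region importance
    gates for three-class diagnosis. A synthetic cohort generator with
    planted differential expression provides ground truth for end-to-end
    validation, and a pipeline driver ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
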