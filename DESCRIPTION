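Package: phagehost
Title: Phage-Host Prediction from a Virus-Prokaryote Heterogeneous Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts prokaryotic hosts for phages and other prokaryotic
    viruses. A virus-prokaryote heterogeneous graph is assembled from
    protein-cluster sharing (hypergeometric test), BLASTN alignment
    evidence, CRISPR-spacer hits and known interactions; node embeddings
    are learned with a light graph-convolution encoder augmented by
    embedding-space contrastive learning (a Bayesian personalized ranking
    objective jointly optimized with an InfoNCE term), and candidate hosts
    are ranked for each query virus with taxonomy-aware evaluation at
    species, genus and family level. Includes a synthetic planted-block
    ecosystem generator for end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
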