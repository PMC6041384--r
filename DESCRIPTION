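Package: readerclust
Title: Individual Differences in Single-Word Reading from Multi-Subject fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying individual differences in
    single-word reading with task-based fMRI and behavioral measures. Provides
    an event-related cohort simulator with latent reader subgroups, first-level
    general linear models with a canonical hemodynamic response, a Bayesian
    multi-subject activation model with a spike-and-slab prior, a spatially
    informed Ising prior over a region-of-interest neighbor network and a
    shared Dirichlet-process-style amplitude mixture, Bayesian false discovery
    rate thresholding, hierarchical subject clustering with silhouette-based
    selection of the number of reader subgroups, representational similarity
    analysis with phonological feature edit distance and semantic cosine model
    matrices, second-level group contrasts with cluster-extent thresholding,
    and reaction-time effect analyses (lexicality, regularity and
    pseudohomophone effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
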