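Package: cytoqnorm
Title: Cluster-Wise Quantile Normalization of Multi-Batch Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes batch effects from mass and flow cytometry experiments
    that carry a shared control sample on every batch. Cells of the control
    samples are clustered with a self-organizing map followed by consensus
    hierarchical metaclustering; within each metacluster and marker, empirical
    quantile distributions are aligned to a goal distribution with monotone
    cubic Hermite (Fritsch-Carlson) splines, and the learned transformations
    are applied to all other samples of the same batch. Includes FCS 3.0/3.1
    reading and FCS 3.1 writing, arcsinh transforms, a binned 1D Earth Mover's
    Distance evaluation with reduction scores, and a synthetic multi-batch
    data generator with ground-truth population labels and monotone,
    population-specific batch distortions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
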