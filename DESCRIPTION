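Package: heatpass
Title: Heat-Kernel Diffusion and Exemplar Message Passing on Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral graph heat kernels turn local edge weights into global
    heat affinities; an exemplar message-passing procedure ("heat passing")
    then discovers the number of clusters, the cluster centers (heat centers)
    and the memberships (heat sinks) simultaneously.  The package also
    provides heat-distance ranking, heat-coordinate embedding,
    clustering-quality indices (accuracy, Rand, silhouette), a common-line
    projection-image distance for cryo-EM class discovery, and synthetic
    generators (Zachary karate club, planted-partition graphs, two-state
    Gaussian-blob phantom projections) so that every component is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
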