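Package: tcrsa
Title: Representational Similarity Analysis of Temporal Community Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting cortical representations of object identity and
    of higher-order temporal community structure in multivariate trial responses.
    Implements constrained quasi-random walks on modular and complete object
    graphs with counterbalancing post-selection, a surrogate generator of
    multivariate parcel responses with known identity and community effects and
    AR(1) trial-to-trial drift, direct linear discriminant analysis (DLDA)
    subspaces with standardized projections, normalized pairwise distances with
    temporal-autocorrelation residualization, community-sensitivity statistics
    with latency-sweep consistency criteria and false-discovery-rate control,
    cross-validated nearest-centroid identity decoding with minimum-statistic
    group inference, and automorphism-averaged distance matrices with
    multidimensional-scaling embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
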