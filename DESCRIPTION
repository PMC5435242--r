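Package: rplnet
Title: Bounded Power-Law Models for Thresholded Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the network structure of functional
    connectivity (connectome) matrices across a sweep of edge-weight
    thresholds: binarisation, degree and node-strength statistics, global
    graph summaries (transitivity, characteristic path length, global
    efficiency, network cost), maximum-likelihood fitting and
    small-sample-corrected AIC selection among three node-statistic
    distribution models (a bounded-support "restricted" power law, an
    exponentially truncated power law, and a plain power law), quantile
    subsampling for noise reduction, and inverse-CDF simulation of network
    cost stability. Includes a synthetic connectivity-matrix generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
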