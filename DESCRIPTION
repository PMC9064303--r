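Package: infoflow
Title: Continuous-Time Information Flow Analysis of Developing Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of transfer entropy and active information storage on
    spike-train recordings in continuous time, using interspike-interval
    history embeddings and nearest-neighbour divergence estimators. Includes
    surrogate-based significance testing and Bonferroni-thresholded functional
    network construction, per-node and population burst detection with
    burst-local transfer entropy, data-driven selection of history embedding
    lengths, longitudinal lock-in and computational-role statistics, and a
    network simulator of Izhikevich neurons developing under spike-timing-
    dependent plasticity that generates synthetic developing-network
    recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
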