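Package: ppmir
Title: Mutual Information Rate Estimation for Coupled Point Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time estimation of the mutual information rate (MIR)
    exchanged between two point processes, computed as the sum of the two
    directed transfer entropy rates obtained from nearest-neighbor entropy
    estimates on inter-event history embeddings. Includes a surrogate-based
    bias-corrected measure (cMIR) with four surrogate engines (local
    permutation of history embeddings, interval shuffling, IAAFT, and an
    autocorrelation-preserving permutation), generators for renewal and
    history-dependent inverse-Gaussian point processes mimicking heartbeat
    and pulse-arrival dynamics, and experiment drivers for bias, coupling
    and sample-size studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
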