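Package: ca1code
Title: Spatiotemporal Input Coding in a Reduced CA1 Pyramidal Neuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced two-layer surrogate of a CA1 pyramidal
    neuron receiving delayed, layer-specific entorhinal (stratum
    lacunosum-moleculare) and Schaffer-collateral (stratum radiatum) input,
    and decodes input features from the output spike pattern. The surrogate
    reproduces the delay-dependent switch between somatic bursting and
    GABA-B mediated spike blocking, and the sensitivity of both regimes to
    clustered versus diffused synapse arrangements. Analysis tools cover
    average firing frequency, burst segmentation and intra-burst
    inter-spike-interval statistics, duty cycle, time-to-first-spike, local
    variation, three-dimensional return maps with normalized entropy,
    nonlinear (delay-embedding, local-constant) prediction error, sigmoid
    delay-response fits, and Spearman-distance complete-linkage clustering
    of median ISI signatures for input classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
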