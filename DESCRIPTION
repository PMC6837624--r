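Package: izhifit
Title: Fitting Izhikevich-Type Neuron Models to Firing-Pattern Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated construction of simple phenomenological neuron models
    (single- and compact multi-compartment Izhikevich models) from quantitative
    firing-pattern phenotypes. Provides a fixed-step simulator with asymmetric
    electrical coupling, spike-train feature extraction (first-spike latency,
    inter-spike intervals, spike-frequency adaptation, burst metrics),
    classification of responses into a transient/steady-state firing-pattern
    taxonomy, a feature-weighted log error with dynamic class-mismatch weights,
    dendritic constraint probes (rheobase, voltage deflection, spike propagation,
    EPSP amplitude, back-propagation attenuation, rebound excitability), an
    evolutionary-algorithm parameter search emitting clouds of accepted models,
    and categorical association statistics (Barnard's unconditional exact test,
    tertile/sign encoding, false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
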