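Package: barrelsim
Title: Clock-Driven Simulation of Balanced Barrel-Cortex Microcircuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and simulates leaky integrate-and-fire network models of
    the rodent whisker barrel system on a fixed 1-ms clock: thalamic drive as
    seeded inhomogeneous Poisson spike trains, exponential-current synapses,
    and inhibitory weights set by the Brunel excitation-inhibition balance
    condition extended to unequal synaptic time constants. Provides builders
    for a single barrel, a full barrel column and a laterally connected chain
    of columns, experiment pipelines for the balance-coefficient sweep, the
    thalamocortical response transformation and lateral propagation through
    the superficial layers, and spike-train analysis (firing rates,
    peristimulus time histograms, windowed spike counts) with a plain-text
    spike-file format.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
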