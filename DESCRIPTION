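Package: delaypop
Title: Stimulus Encoding in Converging Neuronal Populations with Conduction Delays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of how population size, response heterogeneity and axonal
    conduction delays shape stimulus-encoding performance in converging sensory
    populations, developed around p-type electroreceptor afferents of weakly
    electric fish.  Provides single spike-train metrics (Gaussian-kernel firing
    rates, vector strength, interspike-interval statistics, burst fraction,
    spike-triggered averages), Welch cross-spectral estimation with
    stimulus-response coherence and the lower-bound mutual information rate,
    assembly of homogeneous and heterogeneous populations with injected
    Gaussian conduction delays, receptor-position localization and
    conduction-velocity regression from phase or latency data, a leaky
    integrate-and-fire population simulator with finite conduction velocity,
    and a calibrated synthetic generator of P-unit-like afferent responses
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
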