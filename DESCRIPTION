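Package: oepcsim
Title: Modelling Photocapacitor Stimulation of Kv1.3 Channels in Whole-Cell Patch Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical modelling chain for optoelectronic single-cell
    stimulation with organic electrolytic photocapacitors (OEPCs). Provides a
    sequential hidden-Markov gating model of the Kv1.3 potassium channel, a
    whole-cell patch-clamp equivalent circuit with Bessel-filtered output, a
    two-domain (attached/free membrane) model of extracellular photocapacitor
    stimulation with an equivalent-clamp-voltage inversion,
    conductance-voltage (G50) analysis, hybrid particle-swarm parameter
    estimation, and a synthetic-data generator that emulates whole-cell
    recordings under the study's step protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
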