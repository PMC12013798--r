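Package: tuberwave
Title: Travelling-Wave Analysis and Neural-Mass Modelling of Perituberal
    Interictal Discharges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for interictal epileptiform discharges (IEDs)
    recorded on stereo-EEG depth electrodes around cortical tubers. Provides a
    synthetic SEEG generator with known ground truth, EDF+ input/output and
    bipolar montage construction, per-channel spike detection and cross-channel
    grouping, cross-correlation delay estimation with BIC comparison of linear
    spatiotemporal delay models (uniform, depth-to-surface, core-to-periphery),
    a canonical-microcircuit neural mass network model over electrode contacts,
    variational-Laplace model inversion with Bayesian model reduction across
    coupling architectures and input sites, random-effects group model
    selection with exceedance probabilities, and in-silico intrinsic gain
    sweeps probing the transition from spike-wave discharges to seizure-like
    fast rhythms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
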