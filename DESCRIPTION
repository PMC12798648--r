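Package: hopfbrain
Title: Whole-Brain Hopf Models, Latent Embeddings, and In Silico
    Perturbation of Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits whole-brain models of coupled Stuart-Landau (Hopf)
    oscillators to condition-wise functional connectivity with a genetic
    algorithm over resting-state-network grouped bifurcation and coupling
    parameters, mass-produces surrogate functional connectivity matrices by
    dynamical data augmentation, learns low-dimensional variational
    autoencoder embeddings of the connectivity, classifies clinical
    conditions from the latent coordinates with dense neural networks, and
    sweeps periodic in silico perturbations over nodes and forcing
    amplitudes to map the regions whose stimulation reclassifies a
    condition. A synthetic-cohort generator with known ground truth
    (parcellation, modular structural connectome, condition-specific Hopf
    parameters, band-limited BOLD-like recordings) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
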