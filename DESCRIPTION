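Package: strfnet
Title: Spiking Network Models of Auditory Cortical Spectrotemporal
    Receptive Fields
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling rapid task-related plasticity of
    spectrotemporal receptive fields (STRFs) in primary auditory cortex.
    Synthesizes temporally orthogonal ripple combination (TORC) stimuli,
    converts them to stochastic auditory-nerve discharge trains through a
    tonotopic gammatone/Poisson periphery, simulates a fully
    interconnected integrate-and-fire cortical network with alpha
    synapses and integer-coded synaptic strengths, estimates STRFs by
    reverse correlation, fits network parameters to target STRFs with an
    elitist genetic algorithm, and ranks fitted parameters by
    perturbation sensitivity analysis to extract the network changes that
    explain passive-versus-behavioral STRF differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    signal,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
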