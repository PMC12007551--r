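Package: tmsresponse
Title: Average Response Models of Cortical Neurons Under Transcranial
    Magnetic Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples parameterized extracellular electric fields into
    multicompartment cable models of cortical neurons to study their
    activation by transcranial magnetic stimulation (TMS). Provides
    SWC morphology handling with axon myelination, quasipotential
    field coupling, a backward-Euler Hodgkin-Huxley cable solver with
    binary-search threshold estimation, averaged threshold maps and
    recruitment-rate surfaces over field angle and field decay,
    generalized polynomial chaos surrogates with Sobol sensitivity
    indices, and verification of the reduced average model against
    direct per-neuron reference simulation on synthetic cortical
    patches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
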