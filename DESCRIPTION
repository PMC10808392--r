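Package: strainkin
Title: Kinetic-Ensemble Strain Design with Minimal Phenotype Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rational metabolic strain design with ensembles of
    nonlinear kinetic models. Samples thermodynamically consistent steady
    states of a metabolic network (thermodynamics-based flux analysis with
    flux/Gibbs-energy sign coupling), builds kinetic-model ensembles anchored
    to those states by back-calculating saturation-consistent parameters,
    screens models by linearized dynamics, fermentation-data reproduction and
    robustness to enzymatic perturbations, computes metabolic control
    coefficients, and devises enzyme intervention strategies via a
    control-coefficient-based mixed-integer linear program (network response
    analysis) that maximizes product yield while bounding the deviation from
    the reference phenotype. Candidate designs are validated, ranked and
    stress-tested in stiff batch-bioreactor simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
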