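Package: coupmap
Title: Desk-Scale Reconstruction of Blunt Head Impacts with ADC-Based
    Injury Correspondence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs blunt head-impact cases at desk scale and maps
    simulated biomechanical fields onto clinical injury assessment based on
    apparent diffusion coefficient (ADC) maps.  Provides a reduced
    single-pivot fall model for head impact kinematics, an explicit
    central-difference finite-element engine on average-nodal-pressure
    (ANP) linear tetrahedra with hyper-viscoelastic brain, elastoplastic
    skull bone, near-incompressible cerebrospinal fluid and rigid-sphere
    penalty contact, per-element extremum envelopes of the standard
    biomechanical injury measures (pressure, von Mises stress, effective
    strain and strain rate, energy densities), a synthetic generator for
    layered head phantom meshes and ADC lesion volumes, and a
    coup-contrecoup correspondence step that pairs depth-of-exceedance of
    Delta-ADC lesions with strain-rate and tensile-pressure injury
    thresholds.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
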