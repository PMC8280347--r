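#' Material parameters for a tissue region
#'
#' Constitutive parameters for one phantom region.  All tissues share a
#' compressible neo-Hookean volumetric law p = K ln(J)/J; the deviatoric
#' response is neo-Hookean, optionally relaxed by a Prony series (soft
#' tissues) or limited by J2 radial-return plasticity with linear isotropic
#' hardening (skull bone).
#'
#' @param density kg/m^3 (> 0).
#' @param bulk_modulus Pa (> 0).
#' @param shear_modulus Pa (> 0), instantaneous shear modulus G0.
#' @param prony_weights dimensionless relaxation weights g_i with
#'   0 <= sum(g_i) < 1 (empty = purely elastic deviatoric response).
#' @param prony_times relaxation times tau_i in s (> 0), same length as
#'   `prony_weights`.
#' @param yield_stress Pa (> 0) or `NULL` for non-plastic materials.
#' @param hardening_modulus Pa (>= 0), linear isotropic hardening H.
#' @return object of class `material_params`.
#' @export
material_params <- function(density, bulk_modulus, shear_modulus,
                            prony_weights = numeric(0),
                            prony_times = numeric(0),
                            yield_stress = NULL, hardening_modulus = 0) {
  stopifnot(density > 0, bulk_modulus > 0, shear_modulus > 0,
            length(prony_weights) == length(prony_times),
            all(prony_weights >= 0), sum(prony_weights) < 1,
            all(prony_times > 0), hardening_modulus >= 0)
  if (!is.null(yield_stress)) stopifnot(yield_stress > 0)
  structure(list(density = density, bulk_modulus = bulk_modulus,
                 shear_modulus = shear_modulus,
                 prony_weights = as.numeric(prony_weights),
                 prony_times = as.numeric(prony_times),
                 yield_stress = yield_stress,
                 hardening_modulus = hardening_modulus),
            class = "material_params")
}

elastic_constants <- function(E, nu) {
  list(K = E / (3 * (1 - 2 * nu)), G = E / (2 * (1 + nu)))
}

#' Default material set for the layered head phantom
#'
#' Literature-typical parameters: hyper-viscoelastic brain (K = 2.19 GPa,
#' G0 = 10 kPa, one Prony term g1 = 0.8, tau1 = 10 ms), CSF with the speed
#' of sound of water and a very low shear modulus (100 Pa), elastoplastic
#' cortical bone (E = 15 GPa, nu = 0.22, yield 90 MPa, H = 1 GPa) and
#' cancellous bone (E = 1 GPa, nu = 0.24, yield 30 MPa).  Any entry can be
#' overridden via `overrides`, a named list of `material_params`.
#'
#' @param overrides named list replacing individual region materials.
#' @return named list of [material_params()] for regions `cortical`,
#'   `cancellous`, `csf`, `brain`, `ventricle_csf`.
#' @export
default_materials <- function(overrides = list()) {
  cort <- elastic_constants(15e9, 0.22)
  canc <- elastic_constants(1e9, 0.24)
  mats <- list(
    cortical = material_params(1900, cort$K, cort$G,
                               yield_stress = 90e6, hardening_modulus = 1e9),
    cancellous = material_params(1200, canc$K, canc$G,
                                 yield_stress = 30e6, hardening_modulus = 1e9),
    csf = material_params(1000, 2.19e9, 100),
    brain = material_params(1040, 2.19e9, 1e4,
                            prony_weights = 0.8, prony_times = 0.010),
    ventricle_csf = material_params(1000, 2.19e9, 100)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(mats)) stop("unknown material region: ", nm)
    stopifnot(inherits(overrides[[nm]], "material_params"))
    mats[[nm]] <- overrides[[nm]]
  }
  mats
}

#' Case presets for the two reconstructed impacts
#'
#' Case 1: backward fall after a road-traffic collision, head rotating at
#' 30 rad/s about T1, impacting a 15 mm radius solid object (coup injury
#' with skull indentation).  Case 2: fall from height onto the occiput,
#' 15 rad/s, 60 mm radius object (coup-contrecoup injury, no skull
#' deformation).  Both use a 0.2 m T1 lever arm and a 20 ms contact
#' simulation.
#'
#' @param case_id 1 or 2.
#' @return list with elements `condition` ([impact_condition()]),
#'   `materials` ([default_materials()]), `anthropometry`
#'   ([anthropometry()]), and `case_id`.
#' @export
case_preset <- function(case_id) {
  if (!(length(case_id) == 1 && case_id %in% c(1, 2)))
    stop("case_id must be 1 or 2")
  cond <- if (case_id == 1) {
    impact_condition(angular_velocity = 30, lever_arm = 0.2,
                     impactor_radius = 0.015, duration = 0.020)
  } else {
    impact_condition(angular_velocity = 15, lever_arm = 0.2,
                     impactor_radius = 0.060, duration = 0.020)
  }
  list(case_id = as.integer(case_id), condition = cond,
       materials = default_materials(), anthropometry = anthropometry())
}
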