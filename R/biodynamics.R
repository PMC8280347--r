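#' Impact condition of a single-pivot backward fall
#'
#' Describes the head at ground contact after rotating about the first
#' thoracic vertebra (T1): angular velocity about T1, lever arm from T1 to
#' the head centre of mass, the radius of the rigid hemispherical impactor,
#' the unit impact direction (direction of head-centre motion at contact),
#' and the simulated contact duration.
#'
#' @param angular_velocity rad/s, >= 0.
#' @param lever_arm m, distance T1 to head centre of mass (> 0).
#' @param impactor_radius m (> 0).
#' @param impact_direction length-3 unit vector (normalised internally).
#' @param duration s (> 0).
#' @param impactor_center_offset m, extra standoff of the impactor along the
#'   impact direction (0 = initially touching).
#' @return object of class `impact_condition`.
#' @export
impact_condition <- function(angular_velocity, lever_arm = 0.2,
                             impactor_radius = 0.015,
                             impact_direction = c(1, 0, 0),
                             duration = 0.020,
                             impactor_center_offset = 0) {
  stopifnot(angular_velocity >= 0, lever_arm > 0, impactor_radius > 0,
            duration > 0, length(impact_direction) == 3)
  nrm <- sqrt(sum(impact_direction^2))
  if (nrm <= 0) stop("impact_direction must be a non-zero vector")
  structure(list(
    angular_velocity = angular_velocity, lever_arm = lever_arm,
    impactor_radius = impactor_radius,
    impact_direction = impact_direction / nrm,
    duration = duration,
    impactor_center_offset = impactor_center_offset
  ), class = "impact_condition")
}

#' Head anthropometry for the reduced fall model
#'
#' Defaults approximate a 50th-percentile adult male head: mass 4.3 kg,
#' centroidal moment of inertia 0.018 kg m^2 about the rotation axis, and a
#' 0.2 m lever arm from T1 to the head centre of mass.
#'
#' @param head_mass kg (> 0).
#' @param head_centroidal_inertia kg m^2 (>= 0), scalar about the rotation
#'   axis.
#' @param lever_arm m (> 0).
#' @return object of class `anthropometry`.
#' @export
anthropometry <- function(head_mass = 4.3, head_centroidal_inertia = 0.018,
                          lever_arm = 0.2) {
  stopifnot(head_mass > 0, head_centroidal_inertia >= 0, lever_arm > 0)
  structure(list(head_mass = head_mass,
                 head_centroidal_inertia = head_centroidal_inertia,
                 lever_arm = lever_arm),
            class = "anthropometry")
}

#' Head kinematic state at ground contact
#'
#' Converts a single-pivot fall (rigid rotation about T1 at the given
#' angular velocity) into the head's translational centre-of-mass velocity,
#' rigid-body spin, and kinetic energy at the instant of contact.  The
#' centre-of-mass speed is omega * L, directed along the impact direction
#' (perpendicular to the lever arm); the spin is preserved; the kinetic
#' energy is 1/2 m (omega L)^2 + 1/2 I_c omega^2.
#'
#' @param condition an [impact_condition()].
#' @param anthro an [anthropometry()]; its lever arm is overridden by the
#'   condition's.
#' @return object of class `head_impact_state` with fields `com_velocity`
#'   (m/s vector), `angular_velocity` (rad/s vector), `rotation_axis`,
#'   `kinetic_energy` (J).
#' @export
impact_state <- function(condition, anthro = anthropometry()) {
  stopifnot(inherits(condition, "impact_condition"),
            inherits(anthro, "anthropometry"))
  u <- condition$impact_direction
  w <- condition$angular_velocity
  L <- condition$lever_arm
  # rotation axis: any unit vector perpendicular to the impact direction,
  # chosen deterministically; lever direction = axis x u so that
  # omega x lever = omega * L * u at the centre of mass.
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  axis <- c(u[2] * ref[3] - u[3] * ref[2],
            u[3] * ref[1] - u[1] * ref[3],
            u[1] * ref[2] - u[2] * ref[1])
  axis <- axis / sqrt(sum(axis^2))
  v <- w * L * u
  omega_vec <- w * axis
  ke <- 0.5 * anthro$head_mass * sum(v^2) +
    0.5 * anthro$head_centroidal_inertia * w^2
  structure(list(com_velocity = v, angular_velocity = omega_vec,
                 rotation_axis = axis, kinetic_energy = ke),
            class = "head_impact_state")
}

#' Kinetic energy of a head impact state
#'
#' 1/2 m |v|^2 + 1/2 I_c |omega|^2; quadratic in the angular velocity, so
#' KE(c * omega) = c^2 KE(omega).
#'
#' @param state a [impact_state()] result.
#' @param anthro an [anthropometry()].
#' @return energy in J.
#' @export
kinetic_energy <- function(state, anthro = anthropometry()) {
  stopifnot(inherits(state, "head_impact_state"),
            inherits(anthro, "anthropometry"))
  0.5 * anthro$head_mass * sum(state$com_velocity^2) +
    0.5 * anthro$head_centroidal_inertia * sum(state$angular_velocity^2)
}
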