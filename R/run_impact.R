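#' Simulate a blunt head impact
#'
#' The step-2 biomechanics stage: the phantom mesh, carrying the rigid-body
#' velocity field of the fall (centre-of-mass velocity plus spin), impacts a
#' fixed rigid spherical object placed initially touching the head surface
#' along the impact direction.  Runs the explicit solver for the requested
#' duration and returns force/energy/acceleration time histories, field
#' snapshots, and per-element extremum envelopes of all injury measures.
#'
#' @param mesh a `phantom_mesh`.
#' @param materials named list of [material_params()] covering every region.
#' @param head_state a [impact_state()] result (rigid-body kinematics at
#'   contact); alternatively `NULL` with an explicit `velocity` field.
#' @param condition an [impact_condition()]; supplies impactor radius,
#'   impact direction, standoff and duration.
#' @param penalty_stiffness contact penalty, N/m per m^2 of facet area.
#' @param dt_safety CFL safety fraction.
#' @param gravity gravity vector (m/s^2) applied as a body force; `NULL`
#'   (default) applies 9.81 m/s^2 along the impact direction (the head is
#'   falling onto the object).
#' @param n_history approximate number of history samples.
#' @param n_snapshots approximate number of full-field snapshots feeding the
#'   envelopes.
#' @param check_stability abort when the energy budget grows without input.
#' @return object of class `simulation_result`: `history` (data.frame
#'   mirroring the contact-force / displacement / energy / acceleration
#'   time-history figures), `envelope` ([field_envelope()]), `mesh`,
#'   `state` (final), `impactor`, diagnostics (`dt`, `KE0`,
#'   `contact_duration`, `peak_acc_g`, `peak_contact_force`,
#'   `residual_indentation`, `energy_balance_error`).
#' @export
run_impact <- function(mesh, materials, head_state, condition,
                       penalty_stiffness = 1e12, dt_safety = 0.8,
                       gravity = NULL, n_history = 400,
                       n_snapshots = 50, check_stability = TRUE) {
  stopifnot(inherits(condition, "impact_condition"))
  u <- condition$impact_direction
  if (is.null(gravity)) gravity <- 9.81 * u
  # place the impactor touching the head surface along the impact direction
  proj <- mesh$nodes[mesh$boundary_nodes, , drop = FALSE] %*% u
  apex <- mesh$boundary_nodes[which.max(proj)]
  center <- mesh$nodes[apex, ] +
    (condition$impactor_radius + condition$impactor_center_offset) * u
  imp <- impactor(center, condition$impactor_radius, penalty_stiffness)

  # rigid-body initial velocity field v_com + omega x r
  n <- nrow(mesh$nodes)
  vel <- matrix(0, n, 3)
  if (!is.null(head_state)) {
    stopifnot(inherits(head_state, "head_impact_state"))
    mass_n <- .nodal_masses(mesh, materials)
    com <- colSums(mesh$nodes * mass_n) / sum(mass_n)
    w <- head_state$angular_velocity
    r <- sweep(mesh$nodes, 2, com)
    vel <- cbind(w[2] * r[, 3] - w[3] * r[, 2],
                 w[3] * r[, 1] - w[1] * r[, 3],
                 w[1] * r[, 2] - w[2] * r[, 1])
    vel <- sweep(vel, 2, head_state$com_velocity, "+")
  }

  dt <- stable_timestep(mesh, materials, dt_safety)
  nsteps <- ceiling(condition$duration / dt)
  state <- fe_init_state(mesh, vel)
  out <- .fe_run(mesh, materials, state, dt, nsteps, contact = imp,
                 gravity = gravity,
                 hist_stride = max(1L, nsteps %/% n_history),
                 field_stride = max(1L, nsteps %/% n_snapshots),
                 check_stability = check_stability)

  env <- .envelope_from_snapshots(mesh, out)
  hist <- out$history
  hist$contact_force <- sqrt(hist$fcx^2 + hist$fcy^2 + hist$fcz^2)

  balance <- abs(out$KE0 + hist$gravity_work - hist$kinetic_energy -
                   hist$internal_energy - hist$contact_energy)
  res <- structure(list(
    history = hist, envelope = env, mesh = mesh, state = out$state,
    impactor = imp, condition = condition, dt = dt, nsteps = nsteps,
    KE0 = out$KE0, mass = out$mass,
    contact_duration = .contact_duration(hist),
    peak_acc_g = max(hist$acc_g),
    peak_contact_force = max(hist$contact_force),
    energy_balance_error = max(balance) / max(out$KE0, 1e-12)
  ), class = "simulation_result")
  res$residual_indentation <- residual_indentation(res)
  res
}

.nodal_masses <- function(mesh, materials) {
  mats <- .region_materials(mesh, materials)
  rho <- vapply(mats, `[[`, 0, "density")[mesh$region]
  me <- rho * mesh$volumes / 4
  mn <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    add <- tapply(me, mesh$elems[, a], sum)
    ii <- as.integer(names(add))
    mn[ii] <- mn[ii] + add
  }
  mn
}

# build the per-element envelopes from the field snapshots
.envelope_from_snapshots <- function(mesh, out) {
  m <- nrow(mesh$elems)
  env <- field_envelope(m)
  ns <- out$n_snaps
  if (ns == 0) return(env)
  for (k in seq_len(ns)) {
    F <- out$snapF[, ((k - 1) * 9 + 1):(k * 9), drop = FALSE]
    L <- out$snapL[, ((k - 1) * 9 + 1):(k * 9), drop = FALSE]
    S <- out$snapS[, ((k - 1) * 6 + 1):(k * 6), drop = FALSE]
    ed <- out$snapEd[, ((k - 1) * 2 + 1):(k * 2), drop = FALSE]
    env <- update_envelope(env, .measures_slice(F, L, S, ed),
                           out$snap_t[k])
  }
  env
}

# all Table-style scalar measures for one snapshot (m x 9 F, m x 9 L,
# m x 6 sigma, m x 2 accumulated energy densities)
.measures_slice <- function(F, L, S, ed) {
  # Green-Lagrange strain E = (F'F - I)/2 in n x 6 form
  E <- cbind(
    (F[, 1]^2 + F[, 2]^2 + F[, 3]^2 - 1) / 2,
    (F[, 4]^2 + F[, 5]^2 + F[, 6]^2 - 1) / 2,
    (F[, 7]^2 + F[, 8]^2 + F[, 9]^2 - 1) / 2,
    (F[, 1] * F[, 4] + F[, 2] * F[, 5] + F[, 3] * F[, 6]) / 2,
    (F[, 1] * F[, 7] + F[, 2] * F[, 8] + F[, 3] * F[, 9]) / 2,
    (F[, 4] * F[, 7] + F[, 5] * F[, 8] + F[, 6] * F[, 9]) / 2)
  evE <- sym_eigenvalues(E)
  eff <- effective_strain(E)
  ss <- stress_scalars(S)
  rr <- rate_scalars(L)
  cbind(pressure = ss$pressure, von_mises = ss$von_mises,
        max_shear_stress = ss$max_shear_stress,
        first_principal_strain = evE[, 1],
        effective_strain = eff,
        first_principal_strain_rate = rr$first_principal_strain_rate,
        effective_strain_rate = rr$effective_strain_rate,
        max_shear_strain_rate = rr$max_shear_strain_rate,
        strain_times_rate = eff * rr$effective_strain_rate,
        dilatational_energy_density = ed[, 1],
        distortional_energy_density = ed[, 2])
}

# time from first contact until the contact force first returns to (near)
# zero after its peak
.contact_duration <- function(hist) {
  fc <- hist$contact_force
  if (is.null(fc)) fc <- sqrt(hist$fcx^2 + hist$fcy^2 + hist$fcz^2)
  on <- which(fc > 1e-9)
  if (!length(on)) return(0)
  pk <- which.max(fc)
  rel <- which(fc < 1e-3 * max(fc) & seq_along(fc) > pk)
  t_end <- if (length(rel)) hist$time_s[rel[1]] else hist$time_s[length(fc)]
  t_end - hist$time_s[on[1]]
}

#' Residual skull indentation
#'
#' Removes the best-fit rigid-body motion (Kabsch fit over the skull-region
#' nodes) from the final configuration and reports the largest inward
#' normal displacement of the outer surface — the permanent (plastic)
#' indentation left by the impact.
#'
#' @param result a [run_impact()] result.
#' @param regions region labels counted as skull for the rigid fit.
#' @return indentation in m (>= 0).
#' @export
residual_indentation <- function(result,
                                 regions = c("cortical", "cancellous")) {
  mesh <- result$mesh
  ridx <- which(mesh$region_labels %in% regions)
  if (!length(ridx)) ridx <- seq_along(mesh$region_labels)
  sk_nodes <- sort(unique(as.integer(
    mesh$elems[mesh$region %in% ridx, , drop = FALSE])))
  X <- mesh$nodes[sk_nodes, , drop = FALSE]
  x <- result$state$x[sk_nodes, , drop = FALSE]
  # Kabsch: rotation + translation minimising |x - (X R + t)|
  Xc <- colMeans(X); xc <- colMeans(x)
  H <- t(sweep(X, 2, Xc)) %*% sweep(x, 2, xc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  u_res <- sweep(x, 2, xc) %*% R  # back to reference frame, zero-mean
  u_res <- u_res - sweep(X, 2, Xc)
  # outward nodal normals on the boundary (reference, area weighted)
  tri <- mesh$boundary_facets
  a <- mesh$nodes[tri[, 2], ] - mesh$nodes[tri[, 1], ]
  b <- mesh$nodes[tri[, 3], ] - mesh$nodes[tri[, 1], ]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nn <- matrix(0, nrow(mesh$nodes), 3)
  for (j in 1:3) for (c3 in 1:3) {
    add <- tapply(nrm[, c3], tri[, j], sum)
    ii <- as.integer(names(add))
    nn[ii, c3] <- nn[ii, c3] + add
  }
  bn <- intersect(mesh$boundary_nodes, sk_nodes)
  nb <- nn[bn, , drop = FALSE]
  nb <- nb / pmax(sqrt(rowSums(nb^2)), 1e-30)
  pos <- match(bn, sk_nodes)
  inward <- -rowSums(u_res[pos, , drop = FALSE] * nb)
  max(0, max(inward))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d tets, %d steps of dt = %.3g us\n",
              nrow(x$mesh$elems), x$nsteps, x$dt * 1e6))
  cat(sprintf("  initial KE        %.1f J\n", x$KE0))
  cat(sprintf("  peak contact force %.2f kN\n", x$peak_contact_force / 1e3))
  cat(sprintf("  peak COM acceleration %.0f g\n", x$peak_acc_g))
  cat(sprintf("  contact duration  %.2f ms\n", x$contact_duration * 1e3))
  cat(sprintf("  residual indentation %.2f mm\n",
              x$residual_indentation * 1e3))
  cat(sprintf("  energy balance error %.2f%% of KE0\n",
              x$energy_balance_error * 100))
  invisible(x)
}

#' Write the time histories of a simulation as CSV
#'
#' Columns mirror the standard reporting figures: contact-force components,
#' centre-of-mass displacement, kinetic and per-region internal energy, and
#' head acceleration in g.
#'
#' @param result a [run_impact()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
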