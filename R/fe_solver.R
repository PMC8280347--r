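#' Explicit finite-element engine
#'
#' The solver integrates the equations of motion with the explicit central
#' difference scheme on a lumped (row-sum) mass matrix.  Average nodal
#' pressure (ANP) linear tetrahedra evaluate the volumetric response from
#' volume-weighted node averages of the element volume ratio J, restricted
#' within each material group, which relieves the volumetric locking of
#' standard linear tetrahedra in nearly incompressible tissue and carries no
#' hourglass modes.  Soft tissues use a compressible neo-Hookean deviatoric
#' response relaxed by a Prony series; skull bone uses finite-strain J2
#' radial-return plasticity with linear isotropic hardening; contact with
#' the rigid spherical impactor is a frictionless nodal penalty.
#'
#' @name fe_solver
NULL

# region materials as an ordered list matching mesh$region_labels
.region_materials <- function(mesh, materials) {
  missing <- setdiff(mesh$region_labels, names(materials))
  if (length(missing))
    stop("no material parameters for region(s): ",
         paste(missing, collapse = ", "))
  materials[mesh$region_labels]
}

#' Stable explicit time step (CFL)
#'
#' safety * min over elements of h_char / c, with dilatational wave speed
#' c = sqrt((K + 4 G0/3) / rho) of the element's material and h_char the
#' element's minimum altitude.
#'
#' @param mesh a `phantom_mesh`.
#' @param materials named list of [material_params()] covering every region.
#' @param safety fraction in (0, 1].
#' @return time step in s.
#' @export
stable_timestep <- function(mesh, materials, safety = 0.8) {
  if (!(safety > 0 && safety <= 1)) stop("safety must be in (0, 1]")
  if (any(mesh$volumes <= 0))
    stop("degenerate element (zero volume): element ",
         which(mesh$volumes <= 0)[1])
  mats <- .region_materials(mesh, materials)
  c_reg <- vapply(mats, function(m)
    sqrt((m$bulk_modulus + 4 * m$shear_modulus / 3) / m$density), 0)
  safety * min(mesh$h_char / c_reg[mesh$region])
}

# ANP node/material-group slots: one averaging slot per (node, region) pair.
# With anp = FALSE every element corner gets its own slot, which reduces the
# volumetric response to the standard (element-wise) linear tetrahedron.
.anp_slots <- function(mesh, anp = TRUE) {
  if (!anp) {
    m <- nrow(mesh$elems)
    return(list(slot_of = matrix(seq_len(4L * m), m, 4L), nslots = 4L * m,
                slot_region = rep(mesh$region, 4),
                slot_node = as.integer(mesh$elems)))
  }
  key <- paste(as.integer(mesh$elems), rep(mesh$region, 4))
  uk <- unique(key)
  slot <- matrix(match(key, uk), ncol = 4L)
  first <- match(uk, key)
  list(slot_of = slot, nslots = length(uk),
       slot_region = rep(mesh$region, 4)[first],
       slot_node = as.integer(mesh$elems)[first])
}

# reference shape-function gradients and volumes (R mirror of the solver
# precomputation, used by the closed-form checks and anp_pressure)
.mesh_gradN <- function(mesh) {
  m <- nrow(mesh$elems)
  gradN <- array(0, c(m, 4, 3))
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    D <- t(X[2:4, ]) - X[1, ]
    Di <- solve(D)
    gradN[e, 2:4, ] <- Di
    gradN[e, 1, ] <- -colSums(Di)
  }
  gradN
}

# deformation gradients of all elements at nodal positions x (n x 3),
# returned m x 9 column-major
.elem_def_grad <- function(mesh, x, gradN = .mesh_gradN(mesh)) {
  m <- nrow(mesh$elems)
  F <- matrix(0, m, 9)
  for (a in 1:4) {
    xa <- x[mesh$elems[, a], , drop = FALSE]
    for (j in 1:3) for (i in 1:3)
      F[, (j - 1) * 3 + i] <- F[, (j - 1) * 3 + i] + xa[, i] * gradN[, a, j]
  }
  F
}

.det3_rows <- function(F) {
  F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
    F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
    F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
}

#' Average-nodal-pressure field
#'
#' Evaluates the ANP volumetric response at the current nodal positions:
#' each node's volume ratio Jbar is the reference-volume-weighted average of
#' adjacent-element J over elements of the same material group, and the
#' nodal volumetric stress is K ln(Jbar)/Jbar (tension positive).  Nodes on
#' material-group boundaries carry one value per group.
#'
#' @param mesh a `phantom_mesh`.
#' @param materials named list of [material_params()].
#' @param x current nodal positions (defaults to the reference mesh).
#' @return data.frame with columns `node`, `region`, `Jbar`,
#'   `volumetric_stress` (Pa, tension positive), and `pressure`
#'   (compression positive, = -volumetric_stress).
#' @export
anp_pressure <- function(mesh, materials, x = mesh$nodes) {
  mats <- .region_materials(mesh, materials)
  F <- .elem_def_grad(mesh, x)
  J <- .det3_rows(F)
  if (any(J <= 0)) stop("element inversion (J <= 0) in element ",
                        which(J <= 0)[1])
  sl <- .anp_slots(mesh)
  num <- den <- numeric(sl$nslots)
  for (a in 1:4) {
    s <- sl$slot_of[, a]
    num_add <- tapply(mesh$volumes * J, s, sum)
    den_add <- tapply(mesh$volumes, s, sum)
    ii <- as.integer(names(num_add))
    num[ii] <- num[ii] + num_add
    den[ii] <- den[ii] + den_add
  }
  Jbar <- num / den
  if (any(Jbar <= 0)) stop("non-positive averaged volume ratio")
  K <- vapply(mats, `[[`, 0, "bulk_modulus")[sl$slot_region]
  sv <- K * log(Jbar) / Jbar
  data.frame(node = sl$slot_node, region = sl$slot_region, Jbar = Jbar,
             volumetric_stress = sv, pressure = -sv)
}

#' Hyper-viscoelastic stress update at a material point
#'
#' Compressible neo-Hookean response: volumetric Cauchy stress
#' K ln(J)/J (no nodal averaging at point level), deviatoric instantaneous
#' Kirchhoff stress G0 dev(J^{-2/3} F F') relaxed by Prony-series internal
#' variables updated with the midpoint exponential recurrence.  The result
#' is frame-indifferent: sigma(R F) = R sigma(F) R'.
#'
#' @param F 3x3 deformation gradient, det F > 0.
#' @param history list as returned (`tau0` and `h`), or `NULL` to start
#'   from a virgin state.
#' @param params a [material_params()].
#' @param dt time step s.
#' @return list with `sigma` (3x3 Cauchy stress) and updated `history`.
#' @export
tissue_stress <- function(F, history, params, dt) {
  stopifnot(inherits(params, "material_params"))
  J <- det(F)
  if (J <= 0) stop("deformation gradient has non-positive determinant")
  nt <- length(params$prony_weights)
  if (is.null(history))
    history <- list(tau0 = matrix(0, 3, 3),
                    h = replicate(max(nt, 1), matrix(0, 3, 3),
                                  simplify = FALSE))
  bb <- J^(-2 / 3) * tcrossprod(F)
  tau0 <- params$shear_modulus * (bb - sum(diag(bb)) / 3 * diag(3))
  if (nt == 0) {
    seff <- tau0
  } else {
    seff <- (1 - sum(params$prony_weights)) * tau0
    for (q in seq_len(nt)) {
      efa <- exp(-dt / params$prony_times[q])
      ema <- exp(-dt / (2 * params$prony_times[q]))
      history$h[[q]] <- efa * history$h[[q]] + ema * (tau0 - history$tau0)
      seff <- seff + params$prony_weights[q] * history$h[[q]]
    }
  }
  history$tau0 <- tau0
  sv <- params$bulk_modulus * log(J) / J
  list(sigma = seff / J + sv * diag(3), history = history)
}

#' J2 radial-return plastic stress update
#'
#' Stress-space radial return with linear isotropic hardening: if the trial
#' von Mises stress exceeds sigma_y + H ebar the deviator is scaled back to
#' the updated yield surface and the accumulated plastic strain grows by
#' (vm_trial - yield)/(3 G + H).  The returned von Mises stress never
#' exceeds sigma_y + H ebar_new and the plastic strain and dissipation are
#' non-decreasing.
#'
#' @param sigma_trial 3x3 symmetric trial Cauchy stress.
#' @param state list with `ebar` (accumulated plastic strain) and
#'   `dissipation` (J/m^3), or `NULL` for a virgin state.
#' @param params a [material_params()] with a yield stress.
#' @return list with `sigma` and updated `state`.
#' @export
plastic_update <- function(sigma_trial, state, params) {
  stopifnot(inherits(params, "material_params"))
  if (is.null(params$yield_stress))
    stop("material has no yield stress; plastic update undefined")
  if (is.null(state)) state <- list(ebar = 0, dissipation = 0)
  p <- sum(diag(sigma_trial)) / 3
  s <- sigma_trial - p * diag(3)
  vm <- sqrt(1.5 * sum(s * s))
  y <- params$yield_stress + params$hardening_modulus * state$ebar
  if (vm <= y) return(list(sigma = sigma_trial, state = state))
  G <- params$shear_modulus
  H <- params$hardening_modulus
  debar <- (vm - y) / (3 * G + H)
  ynew <- y + H * debar
  s_new <- s * (ynew / vm)
  state$ebar <- state$ebar + debar
  state$dissipation <- state$dissipation + ynew * debar
  list(sigma = s_new + p * diag(3), state = state)
}

#' Contact forces against a rigid spherical impactor
#'
#' For each outer-surface node penetrating the sphere by
#' delta = R - |x - center| > 0, a normal force k_p A_node delta acts along
#' the outward radial direction (frictionless).
#'
#' @param mesh a `phantom_mesh`.
#' @param impactor list with `center` (m), `radius` (m),
#'   `penalty_stiffness` (N/m per m^2 of reference facet area), see
#'   [impactor()].
#' @param x current nodal positions (defaults to reference).
#' @return list with `forces` (n x 3), `total` (length-3 total contact
#'   force), `energy` (penalty spring energy, J).
#' @export
contact_forces <- function(mesh, impactor, x = mesh$nodes) {
  fr <- matrix(0, nrow(mesh$nodes), 3)
  tot <- c(0, 0, 0)
  en <- 0
  for (i in mesh$boundary_nodes) {
    d <- x[i, ] - impactor$center
    r <- sqrt(sum(d^2))
    if (r < impactor$radius) {
      if (r < 1e-12) stop("contact node ", i, " coincides with impactor centre")
      pen <- impactor$radius - r
      fmag <- impactor$penalty_stiffness * mesh$nodal_area[i] * pen
      fr[i, ] <- fmag * d / r
      tot <- tot + fr[i, ]
      en <- en + 0.5 * impactor$penalty_stiffness * mesh$nodal_area[i] * pen^2
    }
  }
  list(forces = fr, total = tot, energy = en)
}

#' Rigid spherical impactor
#'
#' @param center length-3 centre (m).
#' @param radius m (> 0).
#' @param penalty_stiffness N/m per unit reference facet area (> 0).
#' @param velocity length-3 centre velocity (m/s); zero for a fixed
#'   impactor.
#' @return list of class `impactor`.
#' @export
impactor <- function(center, radius, penalty_stiffness = 1e12,
                     velocity = c(0, 0, 0)) {
  stopifnot(radius > 0, penalty_stiffness > 0, length(center) == 3,
            length(velocity) == 3)
  structure(list(center = as.numeric(center), radius = radius,
                 penalty_stiffness = penalty_stiffness,
                 velocity = as.numeric(velocity)),
            class = "impactor")
}

#' Initialise a simulation state
#'
#' @param mesh a `phantom_mesh`.
#' @param velocity initial nodal velocities: n x 3 matrix, or a length-3
#'   vector applied uniformly.
#' @param x initial nodal positions (defaults to the reference mesh).
#' @return list of class `sim_state` understood by [fe_step()] and
#'   [run_impact()].
#' @export
fe_init_state <- function(mesh, velocity = c(0, 0, 0), x = mesh$nodes) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  if (is.null(dim(velocity)))
    velocity <- matrix(velocity, n, 3, byrow = TRUE)
  ident <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  be <- matrix(rep(c(1, 1, 1, 0, 0, 0), m), m, 6, byrow = TRUE)
  structure(list(
    x = x, v = velocity, t = 0,
    Fprev = as.numeric(t(matrix(rep(ident, m), m, 9, byrow = TRUE))),
    sigprev = numeric(0),
    tau0 = numeric(m * 6), hvis = numeric(0), be = as.numeric(t(be)),
    ebar = numeric(m), edil = numeric(m), edist = numeric(m),
    W_int = 0, Wp = 0, Wgrav = 0, IE_region = numeric(0)
  ), class = "sim_state")
}

# low-level driver shared by fe_step and run_impact
.fe_run <- function(mesh, materials, state, dt, nsteps,
                    contact = NULL, gravity = c(0, 0, 0), damping = 0,
                    fext = NULL, fixed_nodes = integer(0), fixed_dofs = NULL,
                    hist_stride = max(1L, nsteps %/% 400L),
                    field_stride = 0L, check_stability = FALSE,
                    stability_tol = 0.05, anp = TRUE) {
  mats <- .region_materials(mesh, materials)
  sl <- .anp_slots(mesh, anp)
  con <- if (is.null(contact)) {
    list(enabled = FALSE, center = c(0, 0, 0), velocity = c(0, 0, 0),
         radius = 1, penalty_stiffness = 0)
  } else {
    list(enabled = TRUE, center = contact$center,
         velocity = contact$velocity, radius = contact$radius,
         penalty_stiffness = contact$penalty_stiffness)
  }
  res <- cpp_fe_run(mesh$nodes, mesh$elems, mesh$region, unname(mats), state,
                    dt, as.integer(nsteps), sl$slot_of, sl$nslots,
                    sl$slot_region, mesh$nodal_area,
                    as.integer(mesh$boundary_nodes), con,
                    as.numeric(gravity), damping, fext,
                    as.integer(fixed_nodes), fixed_dofs,
                    as.integer(hist_stride),
                    as.integer(field_stride), check_stability, stability_tol)
  hist <- as.data.frame(res$hist)
  names(hist) <- c("time_s", "fcx", "fcy", "fcz", "ux", "uy", "uz",
                   "kinetic_energy", "internal_energy", "contact_energy",
                   "plastic_dissipation", "gravity_work", "acc_g",
                   paste0("ie_", mesh$region_labels))
  state <- res$state
  class(state) <- "sim_state"
  list(history = hist, state = state, snap_t = res$snap_t,
       snapF = res$snapF, snapL = res$snapL, snapS = res$snapS,
       snapEd = res$snapEd, n_snaps = res$n_snaps, KE0 = res$KE0,
       mass = res$mass)
}

#' Advance a simulation state by explicit time steps
#'
#' One (or more) central-difference updates: internal + contact + gravity
#' forces, lumped-mass accelerations, velocity and position updates, with
#' deformation gradients, viscoelastic/plastic history and energy
#' accumulators refreshed.  `dt` must not exceed [stable_timestep()].
#'
#' @param mesh a `phantom_mesh`.
#' @param materials named list of [material_params()].
#' @param state a [fe_init_state()] result (or a previously returned state).
#' @param dt time step (s).
#' @param nsteps number of steps to take.
#' @param ... further arguments passed to the driver: `contact`
#'   (an [impactor()]), `gravity`, `damping`, `fext`, `fixed_nodes`.
#' @return updated `sim_state` (with `$history` attribute of the sub-run).
#' @export
fe_step <- function(mesh, materials, state, dt, nsteps = 1L, ...) {
  out <- .fe_run(mesh, materials, state, dt, nsteps, hist_stride = nsteps, ...)
  st <- out$state
  attr(st, "history") <- out$history
  st
}
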