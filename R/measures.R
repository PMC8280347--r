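#' Biomechanical injury measures
#'
#' Scalar measures computed from finite-strain kinematics and Cauchy stress,
#' following the usual conventions of impact biomechanics: strains are
#' Green-Lagrange (large-strain), stresses are Cauchy, the strain rate is the
#' symmetrized spatial velocity gradient, and pressure is positive in
#' compression (p = -tr(sigma)/3), so that the injurious "minimum pressure"
#' is the most tensile state.
#'
#' Symmetric tensors are stored either as a 3x3 matrix (single point) or as
#' an n x 6 matrix of Voigt-ordered components (11, 22, 33, 12, 13, 23) for
#' whole-field evaluation.
#'
#' @name measures
NULL

# ---- internal tensor helpers (n x 6 symmetric storage) ----------------------

sym6 <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 3L, ncol(m) == 3L)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("tensor is not symmetric")
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

sym6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

as_sym_rows <- function(x) {
  # accept 3x3 matrix, length-6 vector, or n x 6 matrix; return n x 6
  if (is.matrix(x) && nrow(x) == 3L && ncol(x) == 3L) {
    matrix(sym6(x), 1L, 6L)
  } else if (is.numeric(x) && is.null(dim(x)) && length(x) == 6L) {
    matrix(x, 1L, 6L)
  } else if (is.matrix(x) && ncol(x) == 6L) {
    x
  } else stop("expected a 3x3 symmetric matrix or an n x 6 component matrix")
}

sym_trace <- function(s) s[, 1] + s[, 2] + s[, 3]

sym_dev <- function(s) {
  m <- sym_trace(s) / 3
  s[, 1:3] <- s[, 1:3] - m
  s
}

# double contraction a:b for n x 6 symmetric storage
sym_ddot <- function(a, b) {
  rowSums(a[, 1:3, drop = FALSE] * b[, 1:3, drop = FALSE]) +
    2 * rowSums(a[, 4:6, drop = FALSE] * b[, 4:6, drop = FALSE])
}

#' Eigenvalues of symmetric 3x3 tensor fields
#'
#' Closed-form (trigonometric) eigenvalues for an n x 6 field of symmetric
#' tensors, returned sorted in decreasing order per row.
#'
#' @param s n x 6 matrix of components (11, 22, 33, 12, 13, 23), a length-6
#'   vector, or a single 3x3 symmetric matrix.
#' @return n x 3 matrix of eigenvalues, columns sorted decreasing.
#' @export
sym_eigenvalues <- function(s) {
  s <- as_sym_rows(s)
  a11 <- s[, 1]; a22 <- s[, 2]; a33 <- s[, 3]
  a12 <- s[, 4]; a13 <- s[, 5]; a23 <- s[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(0, nrow(s), 3)
  diag_case <- p <= .Machine$double.eps * pmax(1, abs(q))
  if (any(diag_case)) {
    d <- cbind(a11, a22, a33)[diag_case, , drop = FALSE]
    out[diag_case, ] <- t(apply(d, 1, sort, decreasing = TRUE))
  }
  gen <- !diag_case
  if (any(gen)) {
    pp <- p[gen]; qq <- q[gen]
    b11 <- (a11[gen] - qq) / pp; b22 <- (a22[gen] - qq) / pp
    b33 <- (a33[gen] - qq) / pp
    b12 <- a12[gen] / pp; b13 <- a13[gen] / pp; b23 <- a23[gen] / pp
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- qq + 2 * pp * cos(phi)
    e3 <- qq + 2 * pp * cos(phi + 2 * pi / 3)
    e2 <- 3 * qq - e1 - e3
    out[gen, ] <- cbind(e1, e2, e3)
  }
  out
}

# ---- strain -----------------------------------------------------------------

#' Green-Lagrange strain from a deformation gradient
#'
#' E = (F'F - I)/2, with its deviatoric part E_d = E - tr(E)/3 I.
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @return list with elements `E` and `Ed` (3x3 matrices).
#' @export
green_lagrange <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == 3L))
  if (det(F) <= 0) stop("deformation gradient has non-positive determinant")
  E <- (crossprod(F) - diag(3)) / 2
  Ed <- E - (sum(diag(E)) / 3) * diag(3)
  list(E = E, Ed = Ed)
}

#' Effective (von Mises equivalent) strain
#'
#' sqrt(3/2 * Ed : Ed) for the deviatoric part Ed of a strain tensor; zero
#' iff the strain is purely volumetric.
#'
#' @param E strain tensor: 3x3 matrix, the list returned by
#'   [green_lagrange()], or an n x 6 component matrix.
#' @return numeric vector of effective strains (>= 0).
#' @export
effective_strain <- function(E) {
  if (is.list(E) && !is.null(E$E)) E <- E$E
  s <- sym_dev(as_sym_rows(E))
  sqrt(1.5 * sym_ddot(s, s))
}

# ---- stress -----------------------------------------------------------------

#' Scalar stress measures
#'
#' Pressure (compression positive, p = -tr(sigma)/3), von Mises stress
#' sqrt(3/2 s:s), and maximum shear stress (sigma1 - sigma3)/2 from sorted
#' principal stresses.
#'
#' @param sigma Cauchy stress: symmetric 3x3 matrix or n x 6 component matrix.
#' @return data.frame with columns `pressure`, `von_mises`,
#'   `max_shear_stress`.
#' @export
stress_scalars <- function(sigma) {
  s <- as_sym_rows(sigma)
  p <- -sym_trace(s) / 3
  d <- sym_dev(s)
  vm <- sqrt(pmax(1.5 * sym_ddot(d, d), 0))
  ev <- sym_eigenvalues(s)
  data.frame(pressure = p, von_mises = vm,
             max_shear_stress = (ev[, 1] - ev[, 3]) / 2)
}

# ---- rates ------------------------------------------------------------------

#' Scalar strain-rate measures from a velocity gradient
#'
#' The rate of deformation is D = (L + L')/2.  Returns the first principal
#' strain rate d1, the effective strain rate sqrt(3/2 Dd:Dd), and the maximum
#' (engineering) shear strain rate d1 - d3.  For simple shear at rate
#' gamma-dot this reproduces the characteristic ordering: max shear rate =
#' gamma-dot, effective rate = 0.866 gamma-dot, principal rate =
#' gamma-dot / 2.
#'
#' @param L velocity gradient: 3x3 matrix (not necessarily symmetric) or an
#'   n x 9 matrix of column-major components.
#' @return data.frame with columns `first_principal_strain_rate`,
#'   `effective_strain_rate`, `max_shear_strain_rate`.
#' @export
rate_scalars <- function(L) {
  if (is.matrix(L) && nrow(L) == 3L && ncol(L) == 3L) {
    L <- matrix(as.numeric(L), 1L, 9L)
  }
  stopifnot(is.matrix(L), ncol(L) == 9L)
  if (any(!is.finite(L))) stop("velocity gradient has non-finite entries")
  # column-major 3x3: entries 1..9 = L11 L21 L31 L12 L22 L32 L13 L23 L33
  D <- cbind(L[, 1], L[, 5], L[, 9],
             (L[, 2] + L[, 4]) / 2, (L[, 3] + L[, 7]) / 2,
             (L[, 6] + L[, 8]) / 2)
  d <- sym_dev(D)
  eff <- sqrt(pmax(1.5 * sym_ddot(d, d), 0))
  ev <- sym_eigenvalues(D)
  data.frame(first_principal_strain_rate = ev[, 1],
             effective_strain_rate = eff,
             max_shear_strain_rate = ev[, 1] - ev[, 3])
}

# ---- energy densities -------------------------------------------------------

#' Incremental dilatational and distortional energy densities
#'
#' Accumulates the split of stress power into a volumetric part (pressure
#' times relative volume change) and a deviatoric part (deviatoric stress
#' contracted with the deviatoric strain-rate increment).  Called once per
#' time step with the current Cauchy stress and the strain increment
#' `dE = D * dt` (rate of deformation times step).
#'
#' @param acc list with accumulators `dilatational` and `distortional`
#'   (J/m^3), e.g. `energy_density_init(n)`.
#' @param sigma Cauchy stress (n x 6 or 3x3).
#' @param dE strain increment D*dt over the step (n x 6 or 3x3 symmetric).
#' @return updated accumulator list.
#' @export
energy_densities <- function(acc, sigma, dE) {
  s <- as_sym_rows(sigma)
  de <- as_sym_rows(dE)
  sm <- sym_trace(s) / 3
  dvol <- sym_trace(de)
  sd <- sym_dev(s)
  ded <- sym_dev(de)
  acc$dilatational <- acc$dilatational + sm * dvol
  acc$distortional <- acc$distortional + sym_ddot(sd, ded)
  acc
}

#' @rdname energy_densities
#' @param n number of material points tracked.
#' @export
energy_density_init <- function(n = 1L) {
  list(dilatational = numeric(n), distortional = numeric(n))
}

# ---- envelopes --------------------------------------------------------------

#' Per-element extremum envelopes of injury measures
#'
#' A field envelope tracks, per element and per measure, the running maximum
#' (and additionally the running minimum for pressure, whose most tensile
#' value is the injurious one) together with the time at which each extremum
#' was first attained.  Ties break to the earliest time.
#'
#' @param n_elements number of elements tracked.
#' @param measures character vector of measure names tracked as maxima.
#' @return object of class `field_envelope`.
#' @export
field_envelope <- function(n_elements,
                           measures = c("pressure", "von_mises",
                                        "max_shear_stress",
                                        "first_principal_strain",
                                        "effective_strain",
                                        "first_principal_strain_rate",
                                        "effective_strain_rate",
                                        "max_shear_strain_rate",
                                        "strain_times_rate",
                                        "dilatational_energy_density",
                                        "distortional_energy_density")) {
  mk <- function(fill) matrix(fill, n_elements, length(measures),
                              dimnames = list(NULL, measures))
  structure(list(
    max = mk(-Inf), t_max = mk(NA_real_),
    min_pressure = rep(Inf, n_elements),
    t_min_pressure = rep(NA_real_, n_elements),
    last_time = -Inf, measures = measures, n_elements = n_elements
  ), class = "field_envelope")
}

#' Update a field envelope with one time slice
#'
#' @param env a [field_envelope()].
#' @param values n_elements x measures matrix of instantaneous values; must
#'   contain a `pressure` column for the pressure minimum to be tracked.
#' @param t time of the slice (s); must be >= the previous update time.
#' @return the updated envelope.
#' @export
update_envelope <- function(env, values, t) {
  stopifnot(inherits(env, "field_envelope"))
  if (t < env$last_time) stop("envelope updates must have non-decreasing time")
  values <- as.matrix(values)[, env$measures, drop = FALSE]
  better <- values > env$max
  env$max[better] <- values[better]
  env$t_max[better] <- t
  if ("pressure" %in% colnames(values)) {
    p <- values[, "pressure"]
    lower <- p < env$min_pressure
    env$min_pressure[lower] <- p[lower]
    env$t_min_pressure[lower] <- t
  }
  env$last_time <- t
  env
}

#' Summarise an envelope over element groups
#'
#' Region-wise extremum and time of extremum for each tracked measure
#' (including the pressure minimum), the per-region analogue of a
#' time-to-extremum table.
#'
#' @param env a [field_envelope()].
#' @param region integer or factor of length n_elements.
#' @return data.frame with columns region, measure, extremum, time_ms.
#' @export
envelope_summary <- function(env, region) {
  stopifnot(inherits(env, "field_envelope"), length(region) == env$n_elements)
  region <- as.factor(region)
  rows <- list()
  for (r in levels(region)) {
    sel <- region == r
    for (m in env$measures) {
      v <- env$max[sel, m]
      i <- which.max(v)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, measure = m, extremum = v[i],
        time_ms = env$t_max[sel, m][i] * 1e3)
    }
    pm <- env$min_pressure[sel]
    i <- which.min(pm)
    rows[[length(rows) + 1L]] <- data.frame(
      region = r, measure = "min_pressure", extremum = pm[i],
      time_ms = env$t_min_pressure[sel][i] * 1e3)
  }
  do.call(rbind, rows)
}
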