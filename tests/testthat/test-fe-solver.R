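test_that("stable timestep follows the CFL bound", {
  box <- generate_box_mesh(c(0.02, 0.02, 0.02), c(2, 2, 2))
  # nearly-fluid column: c = sqrt(K/rho) = 1483 m/s for K = 2.2 GPa
  mats <- list(solid = material_params(1000, 2.2e9, 1))
  dt <- stable_timestep(box, mats, safety = 0.5)
  c_d <- sqrt((2.2e9 + 4 / 3) / 1000)
  # independent h_char: min altitude 3V/A_max per element
  h_ind <- sapply(seq_len(nrow(box$elems)), function(e) {
    X <- box$nodes[box$elems[e, ], ]
    V <- abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
    amax <- 0
    for (f in utils::combn(4, 3, simplify = FALSE)) {
      a <- X[f[2], ] - X[f[1], ]; b <- X[f[3], ] - X[f[1], ]
      cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      amax <- max(amax, sqrt(sum(cr^2)) / 2)
    }
    3 * V / amax
  })
  expect_equal(dt, 0.5 * min(h_ind) / c_d, tolerance = 1e-12)
  # halving the edge halves the step
  fine <- generate_box_mesh(c(0.02, 0.02, 0.02), c(4, 4, 4))
  expect_equal(stable_timestep(fine, mats, 0.5), dt / 2, tolerance = 1e-12)
  expect_error(stable_timestep(box, mats, safety = 0), "safety")
})

test_that("ANP nodal pressure follows the volumetric law", {
  mesh <- generate_box_mesh(c(0.02, 0.02, 0.02), c(2, 2, 2))
  mats <- list(solid = material_params(1000, 1e9, 1e5))
  # undeformed: zero everywhere
  p0 <- anp_pressure(mesh, mats)
  expect_lt(max(abs(p0$volumetric_stress)), 1e-9)
  expect_equal(p0$Jbar, rep(1, nrow(p0)))
  # uniform dilatation J = 0.99: identical nodal pressures K ln(J)/J
  J <- 0.99
  x <- mesh$nodes * J^(1 / 3)
  p1 <- anp_pressure(mesh, mats, x)
  expect_equal(p1$volumetric_stress, rep(1e9 * log(J) / J, nrow(p1)),
               tolerance = 1e-10)
  expect_equal(p1$pressure, -p1$volumetric_stress)
})

test_that("tissue stress has the right instantaneous and relaxed limits", {
  params <- material_params(1040, 2.19e9, 1e4,
                            prony_weights = 0.8, prony_times = 0.010)
  # zero strain
  r0 <- tissue_stress(diag(3), NULL, params, 1e-6)
  expect_equal(r0$sigma, matrix(0, 3, 3))
  # small instantaneous shear: sigma12 ~ G0 * gamma
  gam <- 1e-4
  F <- diag(3); F[1, 2] <- gam
  r1 <- tissue_stress(F, NULL, params, 1e-9)
  expect_equal(r1$sigma[1, 2], 1e4 * gam, tolerance = 1e-3)
  # held shear for t >> tau: relaxes to (1 - sum g) G0 gamma
  hist <- r1$history
  dt <- 5e-4
  for (k in seq_len(400)) {  # 0.2 s = 20 tau
    r <- tissue_stress(F, hist, params, dt)
    hist <- r$history
  }
  expect_equal(r$sigma[1, 2], (1 - 0.8) * 1e4 * gam, tolerance = 1e-2)
  expect_error(tissue_stress(diag(c(1, -1, 1)), NULL, params, 1e-6),
               "determinant")
})

test_that("tissue stress is frame indifferent", {
  params <- material_params(1000, 1e8, 1e6)
  set.seed(9)
  F <- diag(3) + matrix(stats::rnorm(9, sd = 0.05), 3, 3)
  s <- tissue_stress(F, NULL, params, 1e-6)$sigma
  for (k in 1:10) {
    R <- random_rotation()
    sR <- tissue_stress(R %*% F, NULL, params, 1e-6)$sigma
    expect_equal(sR, R %*% s %*% t(R), tolerance = 1e-10)
  }
})

test_that("radial-return plasticity pins the stress to the yield surface", {
  params <- material_params(1900, 8.9e9, 6.1e9, yield_stress = 90e6,
                            hardening_modulus = 0)
  # elastic regime: unchanged
  sig <- diag(c(50e6, 0, 0))
  r <- plastic_update(sig, NULL, params)
  expect_identical(r$sigma, sig)
  expect_equal(r$state$ebar, 0)
  # monotonic uniaxial loading past yield with H = 0: von Mises pinned
  state <- NULL
  for (s11 in seq(50e6, 300e6, by = 25e6)) {
    r <- plastic_update(diag(c(s11, 0, 0)), state, params)
    state <- r$state
    vm <- stress_scalars(r$sigma)$von_mises
    expect_lte(vm, 90e6 * (1 + 1e-12))
  }
  expect_gt(state$ebar, 0)
  expect_gt(state$dissipation, 0)
  # with hardening the surface grows but is never exceeded
  ph <- material_params(1900, 8.9e9, 6.1e9, yield_stress = 90e6,
                        hardening_modulus = 1e9)
  rh <- plastic_update(diag(c(400e6, 0, 0)), NULL, ph)
  vmh <- stress_scalars(rh$sigma)$von_mises
  expect_equal(vmh, 90e6 + 1e9 * rh$state$ebar, tolerance = 1e-9)
})

test_that("a load-unload cycle past yield leaves permanent deformation", {
  # stretch a soft elastoplastic cube past yield with an end load, then
  # remove the load and relax: residual elongation remains at ~zero stress
  mesh <- generate_box_mesh(c(0.01, 0.01, 0.01), c(2, 2, 2))
  mats <- list(solid = material_params(1000, 1e8, 3e7, yield_stress = 5e5,
                                       hardening_modulus = 2e7))
  dt <- stable_timestep(mesh, mats, 0.8)
  n <- nrow(mesh$nodes)
  root <- which(mesh$nodes[, 1] < 1e-9)
  fd <- matrix(0L, n, 3); fd[root, 1] <- 1L
  # pin rigid modes
  fd[mesh$nodes[, 1] < 1e-9 & mesh$nodes[, 2] < 1e-9 &
       mesh$nodes[, 3] < 1e-9, ] <- 1L
  fd[mesh$nodes[, 1] < 1e-9 & mesh$nodes[, 2] > 0.01 - 1e-9 &
       mesh$nodes[, 3] < 1e-9, 3] <- 1L
  tip <- which(mesh$nodes[, 1] > 0.01 - 1e-9)
  fext <- matrix(0, n, 3)
  fext[tip, 1] <- 100 / length(tip)  # ~ 1 MPa = 2 sigma_y over the section
  st <- fe_init_state(mesh)
  loaded <- coupmap:::.fe_run(mesh, mats, st, dt, 4000, fixed_dofs = fd,
                              fext = fext, damping = 4000)
  elong_loaded <- mean(loaded$state$x[tip, 1]) - 0.01
  expect_gt(max(loaded$state$ebar), 0)
  unloaded <- coupmap:::.fe_run(mesh, mats, loaded$state, dt, 6000,
                                fixed_dofs = fd, damping = 4000)
  elong_res <- mean(unloaded$state$x[tip, 1]) - 0.01
  expect_gt(elong_res, 0.2 * elong_loaded)   # permanent set
  # plastic strain never decreased
  expect_true(all(unloaded$state$ebar >= loaded$state$ebar - 1e-15))
})

test_that("contact forces follow the penalty definition", {
  mesh <- generate_box_mesh(c(0.02, 0.02, 0.02), c(2, 2, 2))
  far <- impactor(c(1, 1, 1), radius = 0.01)
  r <- contact_forces(mesh, far)
  expect_equal(max(abs(r$forces)), 0)
  expect_equal(r$energy, 0)
  # single penetrating node: |f| = k_p A delta, radially outward
  corner <- which(mesh$nodes[, 1] < 1e-12 & mesh$nodes[, 2] < 1e-12 &
                    mesh$nodes[, 3] < 1e-12)
  A <- mesh$nodal_area[corner]
  imp <- impactor(c(-0.004, 0, 0), radius = 0.005,
                  penalty_stiffness = 1e6 / A)
  r2 <- contact_forces(mesh, imp)
  # delta = 0.005 - 0.004 = 1 mm with k_p A = 1e6 N/m -> 1000 N along +x
  expect_equal(r2$forces[corner, ], c(1000, 0, 0), tolerance = 1e-9)
  expect_equal(r2$total, c(1000, 0, 0), tolerance = 1e-9)
})

test_that("explicit stepping preserves equilibrium, rigid motion and momentum", {
  mesh <- generate_box_mesh(c(0.02, 0.02, 0.02), c(2, 2, 2))
  mats <- list(solid = soft_material())
  dt <- stable_timestep(mesh, mats, 0.8)
  # zero velocity, no forces: state unchanged
  st <- fe_init_state(mesh)
  out <- fe_step(mesh, mats, st, dt, 10)
  expect_equal(out$x, mesh$nodes, tolerance = 1e-14)
  expect_equal(max(abs(out$v)), 0)
  expect_equal(out$W_int, 0, tolerance = 1e-20)
  # rigid translation: F stays identity, no internal energy
  st2 <- fe_init_state(mesh, c(1, 2, -0.5))
  out2 <- fe_step(mesh, mats, st2, dt, 50)
  expect_equal(matrix(out2$Fprev, ncol = 9, byrow = TRUE)[, c(1, 5, 9)],
               matrix(1, nrow(mesh$elems), 3), tolerance = 1e-12)
  expect_lt(abs(out2$W_int), 1e-15)
  expect_equal(out2$x, mesh$nodes + matrix(c(1, 2, -0.5) * dt * 50,
                                           nrow(mesh$nodes), 3, byrow = TRUE),
               tolerance = 1e-12)
  # random velocities, no contact/gravity: linear momentum conserved to 1e-8
  set.seed(13)
  v0 <- matrix(stats::rnorm(nrow(mesh$nodes) * 3), ncol = 3)
  st3 <- fe_init_state(mesh, v0)
  run <- coupmap:::.fe_run(mesh, mats, st3, dt, 400)
  mass <- run$mass
  p0 <- colSums(v0 * mass)
  p1 <- colSums(run$state$v * mass)
  expect_lt(max(abs(p1 - p0)) / max(abs(p0)), 1e-8)
})

test_that("a uniform-deformation patch reproduces the closed-form stress", {
  mesh <- generate_box_mesh(c(0.03, 0.03, 0.03), c(3, 3, 3))
  K <- 1e6; G <- 5e5
  mats <- list(solid = material_params(1000, K, G))
  Fu <- matrix(c(1.02, 0.01, 0, 0.005, 0.99, 0, 0, 0.002, 1.01), 3, 3)
  st <- fe_init_state(mesh, x = mesh$nodes %*% t(Fu))
  out <- coupmap:::.fe_run(mesh, mats, st, dt = 1e-9, nsteps = 1,
                           field_stride = 1)
  S <- out$snapS[, 1:6]
  J <- det(Fu)
  bb <- J^(-2 / 3) * Fu %*% t(Fu)
  sig <- G * (bb - sum(diag(bb)) / 3 * diag(3)) / J + K * log(J) / J * diag(3)
  exact <- c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[1, 3], sig[2, 3])
  expect_lt(max(abs(sweep(S, 2, exact))) / max(abs(exact)), 1e-8)
  # the R-side point update agrees with the solver on the same F
  pt <- tissue_stress(Fu, NULL, mats$solid, 1e-9)$sigma
  expect_equal(c(pt[1, 1], pt[2, 2], pt[3, 3], pt[1, 2], pt[1, 3], pt[2, 3]),
               exact, tolerance = 1e-12)
})

test_that("free axial vibration matches the analytic bar period", {
  mesh <- generate_box_mesh(c(0.1, 0.01, 0.01), c(10, 1, 1))
  G <- 1e6
  mats <- list(solid = material_params(1000, 2 * G / 3, G))  # nu = 0
  Texp <- 4 * 0.1 / sqrt(2 * G / 1000)   # fixed-free quarter-wave
  dt <- stable_timestep(mesh, mats, 0.5)
  fixed <- which(mesh$nodes[, 1] < 1e-9)
  v0 <- matrix(0, nrow(mesh$nodes), 3)
  v0[, 1] <- 0.1; v0[fixed, 1] <- 0
  st <- fe_init_state(mesh, v0)
  out <- coupmap:::.fe_run(mesh, mats, st, dt, ceiling(2.5 * Texp / dt),
                           fixed_nodes = fixed, hist_stride = 1)
  ke <- out$history$kinetic_energy
  mins <- which(diff(sign(diff(ke))) > 0) + 1
  Tm <- 2 * mean(diff(out$history$time_s[mins]))
  expect_lt(abs(Tm - Texp) / Texp, 0.05)
})

test_that("element inversion and degenerate contact raise errors", {
  mesh <- generate_box_mesh(c(0.01, 0.01, 0.01), c(1, 1, 1))
  mats <- list(solid = soft_material())
  # slam the two halves of the cube into each other in one huge step
  vcr <- matrix(0, nrow(mesh$nodes), 3)
  vcr[, 1] <- ifelse(mesh$nodes[, 1] < 0.005, 500, -500)
  st <- fe_init_state(mesh, vcr)
  expect_error(coupmap:::.fe_run(mesh, mats, st, 1e-4, 10), "inversion")
  expect_error(contact_forces(mesh, impactor(mesh$nodes[1, ], 0.005)),
               "centre")
})
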