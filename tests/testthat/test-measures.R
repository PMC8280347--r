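test_that("Green-Lagrange strain matches closed forms and is objective", {
  expect_equal(green_lagrange(diag(3))$E, matrix(0, 3, 3))
  E <- green_lagrange(diag(c(1.1, 1, 1)))$E
  expect_equal(E[1, 1], (1.1^2 - 1) / 2)
  expect_equal(E[2, 2], 0)
  set.seed(42)
  for (k in 1:5) {
    R <- random_rotation()
    expect_lt(max(abs(green_lagrange(R)$E)), 1e-12)
  }
  expect_error(green_lagrange(diag(c(-1, 1, 1))), "determinant")
})

test_that("effective strain follows the deviatoric contraction", {
  expect_equal(effective_strain(0.01 * diag(3)), 0)
  E <- matrix(0, 3, 3); E[1, 2] <- E[2, 1] <- 0.05
  expect_equal(effective_strain(E), sqrt(1.5 * 2 * 0.05^2))
  e <- 0.01
  expect_equal(effective_strain(diag(c(2 * e, -e, -e))), 3 * e)
})

test_that("stress scalars honour the compression-positive sign convention", {
  t <- 5e4
  expect_equal(stress_scalars(t * diag(3))$pressure, -t)   # tension -> negative
  expect_equal(stress_scalars(-t * diag(3))$pressure, t)   # compression -> positive
  s <- stress_scalars(diag(c(7e3, 0, 0)))
  expect_equal(s$von_mises, 7e3)
  expect_equal(s$max_shear_stress, 3.5e3)
  expect_equal(s$pressure, -7e3 / 3)
  tau <- 1.3e4
  ps <- matrix(0, 3, 3); ps[1, 2] <- ps[2, 1] <- tau
  s2 <- stress_scalars(ps)
  expect_equal(s2$pressure, 0)
  expect_equal(s2$von_mises, sqrt(3) * tau)
  expect_equal(s2$max_shear_stress, tau)
  expect_error(stress_scalars(matrix(1:9, 3, 3)), "symmetric")
})

test_that("scalar measures agree with an eigen-decomposition oracle on random tensors", {
  set.seed(7)
  S <- random_sym6(1000, scale = 1e5)
  got <- stress_scalars(S)
  eff <- effective_strain(S)
  ev <- sym_eigenvalues(S)
  for (i in seq_len(1000)) {
    M <- matrix(c(S[i, 1], S[i, 4], S[i, 5],
                  S[i, 4], S[i, 2], S[i, 6],
                  S[i, 5], S[i, 6], S[i, 3]), 3, 3)
    lam <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    dev <- lam - mean(lam)
    vm <- sqrt(1.5 * sum(dev^2))
    expect_equal(ev[i, ], lam, tolerance = 1e-10)
    expect_equal(got$von_mises[i], vm, tolerance = 1e-10)
    expect_equal(eff[i], vm, tolerance = 1e-10)  # same contraction
    expect_equal(got$max_shear_stress[i], (lam[1] - lam[3]) / 2,
                 tolerance = 1e-10)
    expect_equal(got$pressure[i], -mean(lam), tolerance = 1e-10)
  }
})

test_that("scalar measures are invariant under rotation", {
  set.seed(11)
  for (k in 1:20) {
    S <- matrix(stats::rnorm(9), 3, 3); S <- (S + t(S)) / 2
    R <- random_rotation()
    a <- stress_scalars(S); b <- stress_scalars(rotate_sym(S, R))
    expect_equal(unlist(a), unlist(b), tolerance = 1e-10)
    expect_equal(effective_strain(S), effective_strain(rotate_sym(S, R)),
                 tolerance = 1e-10)
  }
})

test_that("strain-rate measures reproduce the simple-shear ordering", {
  # rigid rotation: zero rates
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3)
  r0 <- rate_scalars(W)
  expect_equal(unlist(r0), c(0, 0, 0), ignore_attr = TRUE, tolerance = 1e-12)
  # simple shear v = (gd * y, 0, 0): max shear largest, effective
  # slightly smaller (0.866), principal about one-half
  gd <- 100
  L <- matrix(0, 3, 3); L[1, 2] <- gd
  r <- rate_scalars(L)
  expect_equal(r$max_shear_strain_rate, gd)
  expect_equal(r$effective_strain_rate, sqrt(3) / 2 * gd)
  expect_equal(r$first_principal_strain_rate, gd / 2)
  expect_true(r$max_shear_strain_rate > r$effective_strain_rate)
  expect_true(r$effective_strain_rate > r$first_principal_strain_rate)
  # uniform dilatation flow: zero effective rate
  expect_equal(rate_scalars(0.7 * diag(3))$effective_strain_rate, 0)
})

test_that("energy density accumulators split volumetric and deviatoric work", {
  # pure shear history: no dilatational energy
  acc <- energy_density_init(1)
  tau <- 1e4
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- tau
  dE <- matrix(0, 3, 3); dE[1, 2] <- dE[2, 1] <- 1e-4
  for (k in 1:10) acc <- energy_densities(acc, S, dE)
  expect_equal(acc$dilatational, 0)
  expect_equal(acc$distortional, 10 * 2 * tau * 1e-4)
  # hydrostatic small-strain ramp to theta: dilatational ~ K theta^2 / 2
  K <- 2e9; theta <- 1e-3; nstep <- 2000
  acc <- energy_density_init(1)
  for (k in seq_len(nstep)) {
    th <- theta * (k - 0.5) / nstep
    sig <- K * th * diag(3)           # sigma_m = K * theta
    dE2 <- (theta / nstep / 3) * diag(3)
    acc <- energy_densities(acc, sig, dE2)
  }
  expect_equal(acc$dilatational, 0.5 * K * theta^2, tolerance = 1e-5)
  expect_equal(acc$distortional, 0)
  # closed elastic cycle returns both accumulators to zero
  acc <- energy_density_init(1)
  path <- c(seq(0, theta, length.out = 201), rev(seq(0, theta, length.out = 201))[-1])
  for (k in seq_len(length(path) - 1)) {
    thmid <- (path[k] + path[k + 1]) / 2
    sig <- K * thmid * diag(3) + 3 * K * thmid * (diag(c(1, -0.5, -0.5)))
    dth <- path[k + 1] - path[k]
    dE3 <- dth / 3 * diag(3) + dth * diag(c(1, -0.5, -0.5))
    acc <- energy_densities(acc, sig, dE3)
  }
  scale <- 0.5 * K * theta^2
  expect_lt(abs(acc$dilatational) / scale, 1e-6)
  expect_lt(abs(acc$distortional) / scale, 1e-6)
})

test_that("field envelopes track extrema with earliest-tie times", {
  env <- field_envelope(3, measures = c("pressure", "effective_strain_rate"))
  vals <- function(p, r) cbind(pressure = p, effective_strain_rate = r)
  # constant field: extremum time stays at the first step
  env <- update_envelope(env, vals(c(1, 2, 3), c(0, 0, 0)), 0.001)
  env <- update_envelope(env, vals(c(1, 2, 3), c(0, 0, 0)), 0.002)
  expect_equal(env$t_max[, "pressure"], rep(0.001, 3))
  # triangular pulse peaking at 2.9 ms is timestamped at the peak
  env2 <- field_envelope(1, measures = c("pressure", "effective_strain_rate"))
  tt <- seq(0, 0.006, by = 1e-4)
  pulse <- pmax(0, 1 - abs(tt - 0.0029) / 0.0029)
  for (k in seq_along(tt))
    env2 <- update_envelope(env2, vals(pulse[k], 2 * pulse[k]), tt[k])
  expect_equal(env2$t_max[1, "pressure"], 0.0029, ignore_attr = TRUE)
  expect_equal(env2$max[1, "effective_strain_rate"], 2, ignore_attr = TRUE)
  # idempotence and monotonicity against a brute-force history maximum
  set.seed(3)
  hist <- matrix(stats::rnorm(50 * 4), 50, 4)
  env3 <- field_envelope(4, measures = c("pressure", "effective_strain_rate"))
  for (k in 1:50)
    env3 <- update_envelope(env3, vals(hist[k, ], hist[k, ]), k * 1e-3)
  expect_equal(env3$max[, "pressure"], apply(hist, 2, max),
               ignore_attr = TRUE)
  expect_equal(env3$min_pressure, apply(hist, 2, min), ignore_attr = TRUE)
  env4 <- update_envelope(env3, vals(hist[50, ], hist[50, ]), 0.050)
  expect_equal(env4$max, env3$max)
  expect_error(update_envelope(env3, vals(hist[1, ], hist[1, ]), 0.001),
               "non-decreasing")
})

test_that("strain-times-rate envelope is bounded by the product of envelopes", {
  set.seed(5)
  n <- 20
  env <- field_envelope(n)
  cols <- field_envelope(1)$measures
  for (k in 1:30) {
    es <- abs(stats::rnorm(n)); er <- abs(stats::rnorm(n, sd = 100))
    v <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
    v[, "effective_strain"] <- es
    v[, "effective_strain_rate"] <- er
    v[, "strain_times_rate"] <- es * er
    env <- update_envelope(env, v, k * 1e-3)
  }
  expect_true(all(env$max[, "strain_times_rate"] <=
                    env$max[, "effective_strain"] *
                    env$max[, "effective_strain_rate"] + 1e-12))
})
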