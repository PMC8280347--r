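# shared fixtures, memoised so expensive meshes build once per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_phantom <- function() {
  memo("phantom12", generate_head_phantom(phantom_geometry(), seed = 1))
}

small_phantom <- function() {
  memo("phantom16", generate_head_phantom(
    phantom_geometry(target_edge_length = 0.016), seed = 1))
}

soft_material <- function(E = 1e6, nu = 0.3, rho = 1000, ...) {
  material_params(rho, E / (3 * (1 - 2 * nu)), E / (2 * (1 + nu)), ...)
}

# random symmetric 3x3 tensor in n x 6 component form
random_sym6 <- function(n, scale = 1) {
  cbind(matrix(stats::rnorm(3 * n, sd = scale), n, 3),
        matrix(stats::rnorm(3 * n, sd = scale / 2), n, 3))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rotate_sym <- function(S, R) R %*% S %*% t(R)
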