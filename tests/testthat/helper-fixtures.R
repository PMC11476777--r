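# Shared fixtures for the test suite. Everything is generated in code.

# regular tetrahedron with outward winding, circumradius sqrt(3) * s / ...
make_tetra <- function(scale = 1) {
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(V, F)
}

# open two-triangle patch sharing one interior edge
make_patch <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0.2))
  surface_mesh(V, rbind(c(1, 2, 3), c(2, 1, 4)))
}

# square pyramid whose base diagonal is a coplanar hinge
make_pyramid <- function() {
  V <- rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0), c(0, 0, 1))
  F <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5),
             c(1, 3, 2), c(1, 4, 3))  # base split along the 1-3 diagonal
  surface_mesh(V, F)
}

# icosphere with a labeled bud patch
make_budded <- function(subdivisions = 2, cap_angle = 0.5, radius = 1) {
  init_bud_patch(build_icosphere(subdivisions, radius), c(0, 0, 1), cap_angle)
}

# random rigid motion
random_rigid <- function(V, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(V %*% t(R), 2, rnorm(3), "+")
}

# a mildly perturbed budded sphere used by several mechanics tests
perturbed_budded <- function(sd = 0.02, seed = 42, subdivisions = 2) {
  set.seed(seed)
  mesh <- make_budded(subdivisions)
  mesh$V <- mesh$V + matrix(rnorm(length(mesh$V), sd = sd), ncol = 3)
  mesh
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

expect_valid_mesh <- function(mesh) {
  v <- validate_mesh(mesh)
  expect_true(v$pass, info = paste("validity:", paste(names(v)[!unlist(
    lapply(v, isTRUE))], collapse = ", ")))
  invisible(v)
}
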