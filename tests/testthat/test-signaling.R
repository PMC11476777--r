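test_that("cue field matches the height-power formula", {
  mesh <- make_budded(2)
  cue <- list(umin = 0.1, umax = 1, n_schedule = 2)
  cf <- cue_field(mesh, cue, 1)
  # endpoints: tip face at umax, bottom face at umin (up to face-centre offset)
  expect_equal(max(cf$u), cue$umax, tolerance = 5e-3)
  expect_equal(min(cf$u), cue$umin, tolerance = 5e-3)
  # direct substitution at every face for n = 2
  s <- (cf$HT - cf$Hmin) / cf$Htotal
  expect_equal(cf$u, 0.1 + 0.9 * s^2, tolerance = 1e-12)
  # mid-height face: u = umin + 0.25 (umax - umin) when s = 1/2
  expect_equal(cue_exponent_at(2, 1), 2)
  mid <- which.min(abs(s - 0.5))
  expect_equal(cf$u[mid], 0.1 + 0.9 * s[mid]^2, tolerance = 1e-12)

  # n -> infinity: cue collapses to umin away from the tip
  cf_inf <- cue_field(mesh, list(umin = 0.1, umax = 1, n_schedule = 400), 1)
  away <- s < 0.95
  expect_lt(max(cf_inf$u[away]), 0.1 + 1e-6)

  # degenerate flat geometry is rejected
  flat <- list(V = cbind(runif(10), runif(10), rep(1, 10)),
               F = rbind(c(1L, 2L, 3L)))
  expect_error(cue_field(flat, cue, 1), "degenerate")
})

test_that("cue exponent schedules interpolate piecewise linearly", {
  sched <- list(frames = c(1, 50, 100), n = c(5, 12, 7))
  expect_equal(cue_exponent_at(sched, 1), 5)
  expect_equal(cue_exponent_at(sched, 50), 12)
  expect_equal(cue_exponent_at(sched, 75), 9.5)
  expect_equal(cue_exponent_at(sched, 100), 7)
  expect_equal(cue_exponent_at(sched, 160), 7)   # constant beyond the end
  expect_equal(cue_exponent_at(function(f) f + 1, 4), 5)
})

test_that("cotangent Laplacian annihilates constants and is symmetric", {
  mesh <- build_icosphere(3, 1)
  lap <- assemble_laplacian(mesh)
  expect_lt(max(abs(lap$W %*% rep(3.7, nrow(mesh$V)))), 1e-11)
  expect_equal(max(abs(lap$W - Matrix::t(lap$W))), 0)
  expect_equal(sum(lap$mass), compute_geometry(mesh)$total_area,
               tolerance = 1e-12)
})

test_that("Laplacian reproduces the l = 1 spherical harmonic eigenvalue", {
  # Lap z = -2 z / R^2 on a sphere; relative L2 error < 2% at subdivision 5
  # and decreasing under refinement
  errs <- vapply(3:5, function(s) {
    mesh <- build_icosphere(s, 1)
    lap <- assemble_laplacian(mesh)
    z <- mesh$V[, 3]
    Dz <- as.numeric(lap$W %*% z) / lap$mass
    sqrt(sum(lap$mass * (Dz + 2 * z)^2) / sum(lap$mass * (2 * z)^2))
  }, numeric(1))
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("surface average is exact for lumped linear quadrature", {
  mesh <- build_icosphere(2, 1)
  n <- nrow(mesh$V)
  expect_equal(surface_average(mesh, rep(4.2, n)), 4.2, tolerance = 1e-12)
  expect_equal(surface_average(mesh, mesh$V[, 3]), 0, tolerance = 1e-10)

  # dense per-face linear-interpolation quadrature oracle
  set.seed(8)
  a <- runif(n)
  g <- compute_geometry(mesh)
  dense <- sum(g$face_area * rowMeans(matrix(a[mesh$F], ncol = 3))) /
    g$total_area
  expect_equal(surface_average(mesh, a), dense, tolerance = 1e-10)
})

test_that("reaction-diffusion stepping recovers closed-form limits", {
  mesh <- make_budded(2)
  cue <- cue_field(mesh, list(umin = 0.05, umax = 1, n_schedule = 2), 1)
  n <- nrow(mesh$V)

  # all rates zero: pure diffusion leaves a constant field unchanged
  par0 <- signaling_params(Dc = 0.5, k0 = 0, k1 = 0, k2 = 0, k3 = 0, k4 = 0)
  st <- chemical_state(rep(1.5, n), 1)
  out <- rd_step(mesh, st, cue, par0)
  expect_equal(out$a, rep(1.5, n), tolerance = 1e-10)

  # only basal inactivation: a(t) = a0 exp(-k2 t)
  k2 <- 2
  par_dec <- signaling_params(Dc = 0, k0 = 0, k1 = 0, k2 = k2, k3 = 0, k4 = 0,
                              dt_chem = 1e-3 / k2)
  st <- chemical_state(rep(1, n), 1)
  nsteps <- 100  # integrate to t = 0.1 / k2
  for (i in seq_len(nsteps)) st <- rd_step(mesh, st, cue, par_dec)
  expect_equal(st$a, rep(exp(-k2 * nsteps * 1e-3 / k2), n), tolerance = 1e-4)

  # abar above the set point with b > 0: b strictly increases
  par_b <- signaling_params(k0 = 0, k1 = 0, k2 = 0, k3 = 0, k4 = 5, kss = 0.1)
  st <- chemical_state(rep(1, n), 2)
  out <- rd_step(mesh, st, cue, par_b)
  expect_gt(out$b, 2)
})

test_that("quasi-steady state enforces homeostasis of the surface average", {
  mesh <- make_budded(3, cap_angle = 0.35)
  par <- signaling_params()
  for (n in c(2, 8)) {
    cue <- cue_field(mesh, list(umin = 0.05, umax = 1, n_schedule = n), 1)
    st <- solve_quasi_steady(mesh, chemical_state(rep(par$kss, nrow(mesh$V)), 1),
                             cue, par, tol = 1e-3)
    expect_true(attr(st, "converged"))
    expect_gt(st$b, 0)
    expect_lt(abs(attr(st, "abar") - par$kss), 1e-3)
  }
})

test_that("an unbiased cue with symmetric start stays uniform", {
  mesh <- build_icosphere(2, 1)
  mesh$region <- rep(1L, nrow(mesh$F))  # treat whole sphere as one region
  par <- signaling_params()
  cue <- cue_field(mesh, list(umin = 0.5, umax = 0.5 + 1e-15, n_schedule = 2), 1)
  st <- solve_quasi_steady(mesh, chemical_state(rep(par$kss, nrow(mesh$V)), 1),
                           cue, par, tol = 1e-4)
  spread <- (max(st$a) - min(st$a)) / max(st$a)
  expect_lt(spread, 1e-6)
})

test_that("a steep cue polarizes the activator at the bud tip", {
  mesh <- make_budded(3, cap_angle = 0.35)
  par <- signaling_params()
  cue <- cue_field(mesh, list(umin = 0.05, umax = 1, n_schedule = 8), 1)
  st <- solve_quasi_steady(mesh, chemical_state(rep(par$kss, nrow(mesh$V)), 1),
                           cue, par)
  tip <- which.max(mesh$V[, 3])
  imax <- which.max(st$a)
  # the maximum sits within one edge length of the tip vertex
  edge_len <- mean(compute_geometry(mesh)$edge_length)
  expect_lt(sqrt(sum((mesh$V[imax, ] - mesh$V[tip, ])^2)), 1.001 * edge_len)
})

test_that("polarization height decreases with cue sharpness", {
  mesh <- make_budded(3, cap_angle = 0.35)
  par <- signaling_params()
  ph <- vapply(c(2, 4, 8), function(n) {
    cue <- cue_field(mesh, list(umin = 0.05, umax = 1, n_schedule = n), 1)
    st <- solve_quasi_steady(mesh, chemical_state(rep(par$kss, nrow(mesh$V)), 1),
                             cue, par)
    polarization_height(mesh, st$a, 0.8)$PH
  }, numeric(1))
  expect_true(all(diff(ph) <= 1e-12))
})

test_that("chemical state transfers across remodeling operations", {
  mesh <- make_budded(2, cap_angle = 0.6)
  n <- nrow(mesh$V)
  set.seed(12)
  a <- runif(n)
  st <- chemical_state(a, 1.2)

  # swaps leave the vertex field untouched
  swapped <- run_swaps(mesh, 50, mech_params(), kT = 0.2)
  out <- transfer_state_after_remodel(mesh, st, swapped)
  expect_identical(out$a, st$a)
  expect_identical(out$b, st$b)

  # split: the new vertex gets the mean of its parent endpoints
  k <- which(!mesh$septin)[3]
  pa <- mesh$edges[k, ]
  split <- split_pair(mesh, k, 1.2)
  out2 <- transfer_state_after_remodel(mesh, st, split)
  expect_length(out2$a, n + 1)
  expect_equal(out2$a[n + 1], mean(a[pa]), tolerance = 1e-12)

  # surface-integral drift from one split is bounded by the new mass x value
  m_old <- compute_geometry(mesh)$vertex_dual_area
  m_new <- compute_geometry(split)$vertex_dual_area
  drift <- abs(sum(m_new * out2$a) - sum(m_old * st$a))
  expect_lt(drift, sum(abs(m_new - c(m_old, 0)) * out2$a) +
                   m_new[n + 1] * out2$a[n + 1] + 1e-12)

  # missing provenance is an error when vertices appeared
  stripped <- split
  attr(stripped, "provenance") <- NULL
  expect_error(transfer_state_after_remodel(mesh, st, stripped), "provenance")
})

test_that("the quasi-steady field is stable under Monte Carlo remeshing", {
  mesh <- make_budded(3, cap_angle = 0.35)
  par <- signaling_params()
  cue <- cue_field(mesh, list(umin = 0.05, umax = 1, n_schedule = 8), 1)
  st <- solve_quasi_steady(mesh, chemical_state(rep(par$kss, nrow(mesh$V)), 1),
                           cue, par)
  set.seed(99)
  swapped <- run_swaps(mesh, 100, mech_params(), kT = 0.2)
  st2 <- transfer_state_after_remodel(mesh, st, swapped)
  cue2 <- cue_field(swapped, list(umin = 0.05, umax = 1, n_schedule = 8), 1)
  st2 <- solve_quasi_steady(swapped, st2, cue2, par)
  mass <- compute_geometry(swapped)$vertex_dual_area
  rel_l2 <- sqrt(sum(mass * (st2$a - st$a)^2) / sum(mass * st$a^2))
  expect_lt(rel_l2, 0.01)
})

test_that("degenerate chemical inputs are rejected", {
  expect_error(chemical_state(c(-1, 0), 1))       # negative concentration
  expect_error(chemical_state(c(0, 1), 0))        # absorbing inhibitor state
  expect_error(signaling_params(kss = 0))
})
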