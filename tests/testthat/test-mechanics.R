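test_that("stretching energy matches hand-computed spring values", {
  par <- mech_params(ks = 2, kb = 0, ka = 0, Dm = 0, P = 0)

  # ordinary edge: ks = 2, L0 = 1, L = 1.5 -> (2/2) * 0.5^2 = 0.25
  tet <- make_tetra(scale = 1.5 / (2 * sqrt(2)))  # edge length 1.5
  g <- compute_geometry(tet)
  expect_equal(g$edge_length, rep(1.5, 6), tolerance = 1e-12)
  tet$L0 <- g$edge_length
  tet$L0[1] <- 1
  expect_equal(energy_stretch(tet, g, par), 0.25, tolerance = 1e-12)

  # septin edge: coefficient ks/(2 L0^2); L0 = 2, L = 2.5 -> 0.0625
  tet2 <- make_tetra(scale = 2.5 / (2 * sqrt(2)))
  g2 <- compute_geometry(tet2)
  tet2$L0 <- g2$edge_length
  tet2$L0[1] <- 2
  tet2$septin[1] <- TRUE
  expect_equal(energy_stretch(tet2, g2, par), 0.0625, tolerance = 1e-12)

  # rest state: zero energy
  expect_equal(energy_stretch(make_tetra(), params = par), 0)
})

test_that("septin spring law equals the ordinary law at L0 = 1 and scales as 1/L0^2", {
  par <- mech_params(ks = 3, kb = 0, ka = 0, Dm = 0, P = 0)
  dL <- 0.2
  en_for <- function(L0, septin) {
    tet <- make_tetra(scale = (L0 + dL) / (2 * sqrt(2)))
    g <- compute_geometry(tet)
    tet$L0 <- g$edge_length
    tet$L0[1] <- L0
    tet$septin[1] <- septin
    energy_stretch(tet, g, par)
  }
  expect_equal(en_for(1, TRUE), en_for(1, FALSE), tolerance = 1e-12)
  expect_equal(en_for(2, TRUE), en_for(1, TRUE) / 4, tolerance = 1e-12)
  expect_equal(en_for(0.5, TRUE), en_for(1, TRUE) * 4, tolerance = 1e-12)
})

test_that("bending energy matches the cosine potential", {
  par <- mech_params(ks = 0, kb = 1, ka = 0, Dm = 0, P = 0)
  tet <- make_tetra()
  g <- compute_geometry(tet)
  tet$theta0 <- g$dihedral_angle

  expect_equal(energy_bend(tet, g, par), 0)                  # all at rest
  tet$theta0[1] <- g$dihedral_angle[1] - pi / 2
  expect_equal(energy_bend(tet, g, par), 1, tolerance = 1e-12)  # 1 - cos(pi/2)
  tet$theta0[1] <- g$dihedral_angle[1] - pi
  expect_equal(energy_bend(tet, g, par), 2, tolerance = 1e-12)  # 1 - cos(pi)
})

test_that("area energy matches the harmonic potential and is linear in ka", {
  # one face with ka = 2, A0 = 1, A = 1.5 -> (2/(2*1)) * 0.5^2 = 0.25
  a_edge <- sqrt(1.5 * 4 / sqrt(3))  # equilateral edge with area 1.5
  tet <- make_tetra(scale = a_edge / (2 * sqrt(2)))
  g <- compute_geometry(tet)
  expect_equal(g$face_area[1], 1.5, tolerance = 1e-12)
  tet$A0 <- g$face_area
  tet$A0[1] <- 1
  par <- mech_params(ks = 0, kb = 0, ka = 2, Dm = 0, P = 0)
  expect_equal(energy_area(tet, g, par), 0.25, tolerance = 1e-12)
  par2 <- mech_params(ks = 0, kb = 0, ka = 4, Dm = 0, P = 0)
  expect_equal(energy_area(tet, g, par2), 0.5, tolerance = 1e-12)
  tet$A0[1] <- 0
  expect_error(energy_area(tet, g, par), "rest area")
})

test_that("Morse energy matches the icosahedron closed form", {
  # circumradius-1 icosahedron: edge a = 4/sqrt(10+2*sqrt(5)), second
  # neighbours at phi*a (30 pairs), antipodes at 2 (6 pairs)
  ico <- build_icosphere(0, 1)
  a <- 4 / sqrt(10 + 2 * sqrt(5))
  d2 <- (1 + sqrt(5)) / 2 * a
  D <- as.matrix(dist(ico$V))
  expect_equal(sum(abs(D[upper.tri(D)] - a) < 1e-9), 30)   # edges
  expect_equal(sum(abs(D[upper.tri(D)] - d2) < 1e-9), 30)  # second neighbours
  expect_equal(sum(abs(D[upper.tri(D)] - 2) < 1e-9), 6)    # antipodes

  # range covering the 30 second-neighbour pairs but not the antipodes
  par <- mech_params(ks = 0, kb = 0, ka = 0, Dm = 1, am = 1, Lm = 1.8, P = 0)
  expect_equal(energy_excluded_volume(ico, par),
               30 * (1 - exp(-(d2 - 1.8)))^2, tolerance = 1e-10)

  # pairs exactly at the interaction range contribute zero
  par2 <- mech_params(ks = 0, kb = 0, ka = 0, Dm = 1, am = 1, Lm = d2, P = 0)
  expect_equal(energy_excluded_volume(ico, par2), 0, tolerance = 1e-12)

  # out of range entirely
  par3 <- mech_params(ks = 0, kb = 0, ka = 0, Dm = 1, am = 1, Lm = 1.0, P = 0)
  expect_equal(energy_excluded_volume(ico, par3), 0)

  # compiled kernel agrees with the enumeration implementation
  par4 <- mech_params(ks = 0, kb = 0, ka = 0, Dm = 2, am = 3, Lm = 1.9, P = 0)
  f <- net_forces(ico, par4)
  expect_equal(f$e_morse, energy_excluded_volume(ico, par4), tolerance = 1e-10)
})

test_that("turgor forces follow the per-face lumping rule", {
  mesh <- build_icosphere(2, 1)
  g <- compute_geometry(mesh)

  expect_equal(turgor_forces(mesh, g, mech_params(P = 0)),
               matrix(0, nrow(mesh$V), 3))

  # closed surface: net turgor force vanishes
  Ft <- turgor_forces(mesh, g, mech_params(P = 3))
  expect_lt(sqrt(sum(colSums(Ft)^2)), 1e-9 * 3 * g$total_area)

  # single isolated triangle: each node gets magnitude P*A/3 along the normal
  fake_mesh <- list(V = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    F = rbind(c(1L, 2L, 3L)))
  fake_geom <- list(face_area = 0.5, face_normal = rbind(c(0, 0, 1)))
  Ft1 <- turgor_forces(fake_mesh, fake_geom, mech_params(P = 6))
  expect_equal(Ft1, rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), tolerance = 1e-12)
})

test_that("total energy equals a brute-force per-element summation", {
  set.seed(7)
  patch <- make_patch()
  patch$V <- patch$V + matrix(rnorm(12, sd = 0.1), ncol = 3)
  par <- mech_params(ks = 2.5, kb = 1.3, ka = 0.7, Dm = 0, P = 0)
  g <- compute_geometry(patch)

  # independent naive summation
  E_naive <- 0
  for (e in seq_len(nrow(patch$edges))) {
    L <- sqrt(sum((patch$V[patch$edges[e, 2], ] - patch$V[patch$edges[e, 1], ])^2))
    E_naive <- E_naive + 2.5 / 2 * (L - patch$L0[e])^2
    if (patch$edge_faces[e, 2] > 0) {
      nrm <- function(f) {
        p <- patch$V[patch$F[f, ], ]
        n <- c(pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ]))
        n / sqrt(sum(n^2))
      }
      n1 <- nrm(patch$edge_faces[e, 1]); n2 <- nrm(patch$edge_faces[e, 2])
      th <- acos(min(1, max(-1, sum(n1 * n2))))
      E_naive <- E_naive + 1.3 * (1 - cos(th - patch$theta0[e]))
    }
  }
  for (f in seq_len(nrow(patch$F))) {
    p <- patch$V[patch$F[f, ], ]
    A <- 0.5 * sqrt(sum(pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
    E_naive <- E_naive + 0.7 / (2 * patch$A0[f]) * (A - patch$A0[f])^2
  }

  en <- total_energy(patch, g, par)
  expect_equal(en$total, E_naive, tolerance = 1e-10)
  expect_equal(en$total, en$stretch + en$bend + en$area + en$morse)

  # fresh rest-state mesh has zero energy
  en0 <- total_energy(make_tetra(), params = mech_params(Dm = 0))
  expect_equal(en0$total, 0, tolerance = 1e-12)
})

test_that("analytic forces match central finite differences of the energy", {
  mesh <- perturbed_budded(sd = 0.02, seed = 11, subdivisions = 1)
  par <- mech_params(P = 0, ks = c(mother = 7, bud = 11),
                     kb = c(mother = 2, bud = 0.5), ka = 3,
                     Dm = 0.5, am = 10, Lm = 0.7)
  f <- net_forces(mesh, par)
  h <- 1e-6
  set.seed(3)
  idx <- sample(nrow(mesh$V), 10)
  for (i in idx) for (d in 1:3) {
    mp <- mesh; mp$V[i, d] <- mp$V[i, d] + h
    mm <- mesh; mm$V[i, d] <- mm$V[i, d] - h
    gfd <- -(total_energy(mp, params = par)$total -
             total_energy(mm, params = par)$total) / (2 * h)
    expect_lt(abs(gfd - f$force[i, d]) / max(1, abs(gfd)), 1e-6)
  }
})

test_that("energies are invariant under rigid motions", {
  mesh <- perturbed_budded(sd = 0.02, seed = 5, subdivisions = 1)
  par <- mech_params(P = 0, Dm = 0.5, am = 5, Lm = 0.8)
  e0 <- total_energy(mesh, params = par)
  moved <- mesh
  moved$V <- random_rigid(mesh$V, seed = 9)
  e1 <- total_energy(moved, params = par)
  for (term in c("total", "stretch", "bend", "area", "morse"))
    expect_equal(e1[[term]], e0[[term]], tolerance = 1e-12)
})

test_that("a single overdamped spring relaxes exponentially to rest length", {
  # two nodes, one spring, no faces: c dL/dt = -2 ks (L - L0)
  ks <- 4; cc <- 1.5; L0 <- 1; Lstart <- 1.4; dt <- 1e-4
  nsteps <- 2000L
  res <- budmorph:::.bm_relax(
    rbind(c(0, 0, 0), c(Lstart, 0, 0)),
    matrix(integer(0), 0, 3), rbind(c(1L, 2L)),
    rbind(c(1L, 0L)), rbind(c(0L, 0L)),
    L0, 0, numeric(0), ks, 0, numeric(0),
    0, 0, 0, 0, cc, dt, nsteps, 1e-12, 1e9)
  L_end <- abs(res$V[2, 1] - res$V[1, 1])
  L_exact <- L0 + (Lstart - L0) * exp(-2 * ks / cc * nsteps * dt)
  expect_equal(L_end - L0, L_exact - L0, tolerance = 2e-3)
  # monotone approach
  expect_gt(L_end, L0)
})

test_that("step_overdamped leaves a force-free mesh unchanged and flags blow-ups", {
  mesh <- make_tetra()
  par <- mech_params(P = 0, Dm = 0)
  stepped <- step_overdamped(mesh, par)
  expect_equal(stepped$V, mesh$V)

  bad <- perturbed_budded(sd = 0.05, seed = 2, subdivisions = 1)
  par_huge <- mech_params(P = 0, Dm = 0, dt = 1e308)
  expect_error(step_overdamped(bad, par_huge), "dt")
})

test_that("relaxation is an energy descent at P = 0 and stops at equilibrium", {
  par <- mech_params(P = 0, Dm = 0)
  sphere <- build_icosphere(1, 1)
  out <- relax(sphere, par, max_steps = 50, force_tol = 1e-6)
  expect_true(attr(out, "converged"))
  expect_equal(attr(out, "steps"), 0)

  mesh <- perturbed_budded(sd = 0.03, seed = 13, subdivisions = 1)
  E_prev <- total_energy(mesh, params = par)$total
  for (chunk in 1:8) {
    mesh <- relax(mesh, par, max_steps = 25, force_tol = 1e-9)
    E_now <- total_energy(mesh, params = par)$total
    expect_lte(E_now, E_prev + 1e-12)
    E_prev <- E_now
  }
})

test_that("turgor inflates a sphere to the radius of the radial energy minimum", {
  par <- mech_params(P = 2, Dm = 0, ks = 40, kb = 1, ka = 40)
  sphere <- build_icosphere(2, 1)
  g0 <- compute_geometry(sphere)
  # radial one-parameter oracle: uniform scaling t of a rest-state sphere;
  # the turgor term is -P * Volume(t) with Volume(t) = t^3 * Volume(1)
  E_rad <- function(t)
    40 / 2 * (t - 1)^2 * sum(sphere$L0^2) +
    40 / 2 * (t^2 - 1)^2 * sum(sphere$A0) -
    2 * t^3 * sum(g0$face_area * rowSums(g0$face_normal *
      (sphere$V[sphere$F[, 1], ] + sphere$V[sphere$F[, 2], ] +
       sphere$V[sphere$F[, 3], ]) / 3)) / 3
  t_star <- optimize(E_rad, c(1, 1.5))$minimum
  relaxed <- relax(sphere, par, max_steps = 4000, force_tol = 1e-4)
  r_mean <- mean(sqrt(rowSums(relaxed$V^2)))
  expect_gt(r_mean, 1)          # pressure expands beyond the rest radius
  expect_equal(r_mean, t_star, tolerance = 0.02)
})
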