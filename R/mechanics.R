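#' Mechanical parameters of the cell surface
#'
#' All quantities are in dimensionless simulation units (length unit = the
#' initial mother-cell radius). Stretching and bending stiffness may differ
#' between mother and bud region: a higher stretching-to-bending ratio in
#' the bud is what permits bud emergence under constant turgor.
#'
#' @param c friction coefficient of the overdamped node dynamics.
#' @param ks stretching spring coefficient; scalar or named vector
#'   `c(mother = , bud = )`.
#' @param kb bending coefficient; scalar or `c(mother = , bud = )`.
#' @param ka harmonic area-resistance coefficient.
#' @param Dm,am,Lm Morse self-avoidance well depth, width and interaction
#'   range (pairs farther than `Lm` do not interact; `Lm` is the potential
#'   minimum).
#' @param P turgor pressure (force/area), constant within one cell cycle.
#' @param dt mechanical time step of the forward-Euler integrator.
#' @return an object of class `mech_params`.
#' @export
mech_params <- function(c = 1, ks = c(mother = 40, bud = 60),
                        kb = c(mother = 6, bud = 2), ka = 40,
                        Dm = 0.5, am = 20, Lm = 0.12,
                        P = 4, dt = 5e-4) {
  ks <- expand_region(ks); kb <- expand_region(kb)
  stopifnot(c > 0, all(ks >= 0), all(kb >= 0), ka >= 0, Dm >= 0, am >= 0,
            Lm >= 0, dt > 0)
  structure(list(c = c, ks = ks, kb = kb, ka = ka, Dm = Dm, am = am,
                 Lm = Lm, P = P, dt = dt), class = "mech_params")
}

expand_region <- function(x) {
  if (length(x) == 1) x <- c(mother = unname(x), bud = unname(x))
  stopifnot(all(c("mother", "bud") %in% names(x)))
  x[c("mother", "bud")]
}

# Per-element elastic coefficients. An edge (or hinge) belongs to the bud
# when both incident faces are bud faces. Septin-ring edges use the scaled
# spring law E = ks/(2 L0^2) (L - L0)^2, folded here into the per-edge
# coefficient (mother-side ks, since the ring borders both regions).
elastic_coeffs <- function(mesh, params) {
  r1 <- mesh$region[mesh$edge_faces[, 1]]
  f2 <- mesh$edge_faces[, 2]
  r2 <- ifelse(f2 > 0L, mesh$region[pmax(f2, 1L)], r1)
  edge_bud <- (r1 == REGION_BUD) & (r2 == REGION_BUD)
  ks_edge <- ifelse(edge_bud, params$ks[["bud"]], params$ks[["mother"]])
  sep <- mesh$septin
  ks_edge[sep] <- params$ks[["mother"]] / mesh$L0[sep]^2
  kb_edge <- ifelse(edge_bud, params$kb[["bud"]], params$kb[["mother"]])
  ka_face <- rep(params$ka, nrow(mesh$F))
  list(ks_edge = ks_edge, kb_edge = kb_edge, ka_face = ka_face)
}

#' Stretching (linear spring) energy
#'
#' `E = sum over edges of (ks/2)(L - L0)^2`; septin-ring edges use
#' `ks/(2 L0^2)` in place of `ks/2`.
#'
#' @param mesh a `surface_mesh`.
#' @param geom geometry cache from [compute_geometry()] (recomputed if
#'   missing).
#' @param params a `mech_params`.
#' @param breakdown if `TRUE`, return the per-edge energy vector.
#' @return total energy (scalar), or per-edge vector.
#' @export
energy_stretch <- function(mesh, geom = compute_geometry(mesh), params,
                           breakdown = FALSE) {
  co <- elastic_coeffs(mesh, params)
  per <- 0.5 * co$ks_edge * (geom$edge_length - mesh$L0)^2
  if (breakdown) per else sum(per)
}

#' Bending (cosine hinge) energy
#'
#' `E = sum over hinges of kb (1 - cos(theta - theta0))`, where `theta` is
#' the unsigned angle between the unit normals of the two faces sharing the
#' edge.
#'
#' @inheritParams energy_stretch
#' @return total energy (scalar), or per-hinge vector.
#' @export
energy_bend <- function(mesh, geom = compute_geometry(mesh), params,
                        breakdown = FALSE) {
  co <- elastic_coeffs(mesh, params)
  per <- co$kb_edge * (1 - cos(geom$dihedral_angle - mesh$theta0))
  if (breakdown) per else sum(per)
}

#' Area-resistance (harmonic) energy
#'
#' `E = sum over faces of (ka/(2 A0))(A - A0)^2`.
#'
#' @inheritParams energy_stretch
#' @return total energy (scalar), or per-face vector.
#' @export
energy_area <- function(mesh, geom = compute_geometry(mesh), params,
                        breakdown = FALSE) {
  if (any(mesh$A0 <= 0)) stop("face with zero rest area")
  co <- elastic_coeffs(mesh, params)
  per <- 0.5 * co$ka_face / mesh$A0 * (geom$face_area - mesh$A0)^2
  if (breakdown) per else sum(per)
}

#' Morse excluded-volume energy
#'
#' `E = sum of Dm (1 - exp(-am (L - Lm)))^2` over pairs of vertices that do
#' not share an edge and lie within the interaction range `Lm`. The
#' potential minimum sits at `L = Lm`, so pairs at or beyond range
#' contribute nothing; closer pairs are repelled (self-avoidance).
#'
#' This reference implementation enumerates all pairs; the force kernel
#' used in time stepping employs a spatial hash grid instead.
#'
#' @param mesh a `surface_mesh`.
#' @param params a `mech_params`.
#' @return total energy (scalar).
#' @export
energy_excluded_volume <- function(mesh, params) {
  if (params$Dm == 0 || params$Lm <= 0) return(0)
  D <- as.matrix(stats::dist(mesh$V))
  adj <- matrix(FALSE, nrow(mesh$V), nrow(mesh$V))
  adj[mesh$edges] <- TRUE
  adj[mesh$edges[, 2:1]] <- TRUE
  sel <- upper.tri(D) & !adj & D <= params$Lm
  L <- D[sel]
  sum(params$Dm * (1 - exp(-params$am * (L - params$Lm)))^2)
}

#' Total potential energy with per-term breakdown
#'
#' @inheritParams energy_stretch
#' @return a list with `total`, `stretch`, `bend`, `area`, `morse`.
#' @export
total_energy <- function(mesh, geom = compute_geometry(mesh), params) {
  s <- energy_stretch(mesh, geom, params)
  b <- energy_bend(mesh, geom, params)
  a <- energy_area(mesh, geom, params)
  m <- energy_excluded_volume(mesh, params)
  list(total = s + b + a + m, stretch = s, bend = b, area = a, morse = m)
}

#' Turgor pressure forces
#'
#' Vertex `i` receives `P * sum over incident faces of (A_f/3) n_f`, the
#' outward pressure force lumped from each incident face.
#'
#' @inheritParams energy_stretch
#' @return an n x 3 matrix of per-vertex force vectors.
#' @export
turgor_forces <- function(mesh, geom = compute_geometry(mesh), params) {
  n <- nrow(mesh$V)
  Fv <- matrix(0, n, 3)
  contrib <- geom$face_normal * (geom$face_area / 3) * params$P
  grp <- c(mesh$F[, 1], mesh$F[, 2], mesh$F[, 3])
  acc <- rowsum(rbind(contrib, contrib, contrib), grp)
  Fv[as.integer(rownames(acc)), ] <- acc
  Fv
}

#' Net forces on all vertices (elastic + Morse + turgor)
#'
#' Analytic gradient of the total potential energy plus the turgor force,
#' computed by the compiled kernel.
#'
#' @param mesh a `surface_mesh`.
#' @param params a `mech_params`.
#' @return a list with `force` (n x 3) and the energy breakdown
#'   `e_stretch`, `e_bend`, `e_area`, `e_morse`.
#' @export
net_forces <- function(mesh, params) {
  co <- elastic_coeffs(mesh, params)
  .bm_forces(mesh$V, mesh$F, mesh$edges, mesh$edge_faces, mesh$edge_opp,
             mesh$L0, mesh$theta0, mesh$A0,
             co$ks_edge, co$kb_edge, co$ka_face,
             params$Dm, params$am, params$Lm, params$P)
}

#' One forward-Euler step of the overdamped dynamics
#'
#' `c x_i' = -grad E_total + F_turgor`, discretised as
#' `x <- x + (dt/c) (force)`.
#'
#' @param mesh a `surface_mesh`.
#' @param params a `mech_params`.
#' @return the updated `surface_mesh`.
#' @export
step_overdamped <- function(mesh, params) {
  f <- net_forces(mesh, params)
  Vn <- mesh$V + (params$dt / params$c) * f$force
  if (!all(is.finite(Vn))) {
    disp <- sqrt(rowSums((f$force * params$dt / params$c)^2))
    stop(sprintf(paste0("non-finite positions after step (max displacement",
                        " %.3g); reduce dt"), max(disp[is.finite(disp)], 0)))
  }
  mesh$V <- Vn
  mesh
}

#' Relax the surface towards mechanical equilibrium
#'
#' Iterates forward-Euler overdamped steps until the maximum vertex force
#' magnitude falls below `force_tol` or `max_steps` is reached. If the
#' integration diverges (non-finite positions), the step is retried from
#' the initial state with a halved time step, up to `max_halvings` times.
#'
#' @param mesh a `surface_mesh`.
#' @param params a `mech_params`.
#' @param max_steps maximum number of Euler steps.
#' @param force_tol convergence threshold on the max vertex force.
#' @param max_halvings number of automatic dt-halving retries.
#' @param dmax per-step displacement cap (trust region); steps whose
#'   nominal displacement would exceed `dmax` are shortened, which keeps
#'   locally refined (stiff) elements stable without shrinking the global
#'   time step.
#' @return the relaxed `surface_mesh`, with attributes `steps`, `converged`,
#'   `fmax`, and `energy` (final breakdown).
#' @export
relax <- function(mesh, params, max_steps = 500, force_tol = 1e-3,
                  max_halvings = 4, dmax = 0.01) {
  stopifnot(max_steps >= 1)
  co <- elastic_coeffs(mesh, params)
  dt <- params$dt
  for (try in 0:max_halvings) {
    res <- .bm_relax(mesh$V, mesh$F, mesh$edges, mesh$edge_faces,
                     mesh$edge_opp, mesh$L0, mesh$theta0, mesh$A0,
                     co$ks_edge, co$kb_edge, co$ka_face,
                     params$Dm, params$am, params$Lm, params$P,
                     params$c, dt, as.integer(max_steps), force_tol, dmax)
    if (res$finite) break
    dt <- dt / 2
  }
  if (!res$finite)
    stop("relaxation diverged even after dt halvings; check parameters")
  mesh$V <- res$V
  attr(mesh, "steps") <- res$steps
  attr(mesh, "converged") <- res$converged
  attr(mesh, "fmax") <- res$fmax
  attr(mesh, "energy") <- list(stretch = res$e_stretch, bend = res$e_bend,
                               area = res$e_area, morse = res$e_morse)
  mesh
}
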