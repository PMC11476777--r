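#' Signaling parameters of the Cdc42 activator / global-inhibitor system
#'
#' The active Cdc42 concentration `a` lives on the cell surface and obeys
#' a surface reaction-diffusion equation with a cue-driven activation term,
#' a self-enhancement term, basal inactivation, and inactivation by a
#' well-mixed global inhibitor `b` whose growth is driven by the deviation
#' of the surface average of `a` from a homeostatic set point:
#'
#' da/dt = Dc Lap(a) + k0/(1+(beta u)^-q) + k1/(1+(gamma p a)^-h)
#'         - k2 a - k3 b a,     db/dt = k4 (abar - kss) b,
#' with p = 1/(1+(beta u)^-q).
#'
#' At any steady state with `b > 0` this forces `abar = kss` exactly
#' (integral feedback), which pins the size of the polarized patch; the cue
#' `u` pins its location.
#'
#' @param Dc surface diffusion coefficient of active Cdc42.
#' @param k0 cue-driven activation rate.
#' @param k1 self-enhancement rate.
#' @param k2 basal inactivation rate.
#' @param k3 inhibitor-mediated inactivation rate.
#' @param k4 inhibitor growth rate constant.
#' @param kss homeostatic set point for the surface-average concentration.
#' @param beta cue sensitivity.
#' @param gamma self-enhancement sensitivity.
#' @param q cue Hill exponent.
#' @param h self-enhancement Hill exponent.
#' @param dt_chem chemical time step used by the quasi-steady solver.
#' @return an object of class `signaling_params`.
#' @export
signaling_params <- function(Dc = 0.1, k0 = 1, k1 = 1, k2 = 1, k3 = 2,
                             k4 = 40, kss = 0.02, beta = 2, gamma = 5,
                             q = 4, h = 2, dt_chem = 0.1) {
  stopifnot(Dc >= 0, k0 >= 0, k1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0,
            kss > 0, q > 0, h > 0, dt_chem > 0)
  structure(list(Dc = Dc, k0 = k0, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 kss = kss, beta = beta, gamma = gamma, q = q, h = h,
                 dt_chem = dt_chem), class = "signaling_params")
}

#' Chemical state on the surface
#'
#' @param a per-vertex active Cdc42 concentration (non-negative).
#' @param b global inhibitor concentration (must be positive: `b = 0` is an
#'   absorbing state of its ODE and is rejected as an initial condition).
#' @return an object of class `chemical_state`.
#' @export
chemical_state <- function(a, b) {
  stopifnot(all(is.finite(a)), all(a >= 0), length(b) == 1, b > 0)
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "chemical_state")
}

#' Cue schedule helper: exponent n at a given frame
#'
#' `n_schedule` may be a constant, a function of the frame index, or a
#' piecewise-linear specification `list(frames = c(...), n = c(...))`
#' (linearly interpolated, constant beyond the ends).
#'
#' @param n_schedule schedule specification.
#' @param frame frame index.
#' @return the exponent n(frame).
#' @export
cue_exponent_at <- function(n_schedule, frame) {
  if (is.function(n_schedule)) return(n_schedule(frame))
  if (is.list(n_schedule))
    return(stats::approx(n_schedule$frames, n_schedule$n, xout = frame,
                         rule = 2)$y)
  as.numeric(n_schedule)
}

#' Spatial cue field on faces
#'
#' `u = umin + (umax - umin) ((H_T - H_min)/H_total)^n(t)`, where `H_T` is
#' the z-coordinate of the face centre, `H_min` the z of the bottom of the
#' mother cell, and `H_total` the z-distance from the bud tip to the mother
#' bottom. The cue is maximal at the bud tip and minimal at the bottom of
#' the mother; larger `n` gives a sharper apical gradient.
#'
#' @param mesh a `surface_mesh` (bud axis +z).
#' @param cue list with `umin`, `umax`, `n_schedule` (see
#'   [cue_exponent_at()]); `umin` must be > 0.
#' @param frame frame index for the exponent schedule.
#' @return a list of class `cue_field`: `u` (per-face), `n`, `HT`, `Hmin`,
#'   `Htotal`.
#' @export
cue_field <- function(mesh, cue, frame = 1) {
  n <- cue_exponent_at(cue$n_schedule, frame)
  HT <- (mesh$V[mesh$F[, 1], 3] + mesh$V[mesh$F[, 2], 3] + mesh$V[mesh$F[, 3], 3]) / 3
  # normalise by the face-centre extremes so the tip face sits exactly at
  # umax and the bottom face exactly at umin
  Hmin <- min(HT)
  Htip <- max(HT)
  Htotal <- Htip - Hmin
  if (Htotal <= 0) stop("degenerate mesh: bud tip and mother bottom coincide")
  s <- pmin(1, pmax(0, (HT - Hmin) / Htotal))
  u <- cue$umin + (cue$umax - cue$umin) * s^n
  structure(list(u = u, n = n, HT = HT, Hmin = Hmin, Htotal = Htotal,
                 umin = cue$umin, umax = cue$umax), class = "cue_field")
}

#' Assemble the cotangent Laplace-Beltrami operator
#'
#' Finite-element weak form on the triangulated surface: symmetric weight
#' matrix `W` with `w_ij = (cot alpha_ij + cot beta_ij)/2` and zero row
#' sums, plus barycentric lumped vertex masses summing to the total surface
#' area. The operator approximates `Lap(a) ~ M^-1 W a`. Cotangents of
#' near-degenerate corner angles (below ~0.057 degrees) are clamped with a
#' warning.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `W` (sparse symmetric `dgCMatrix`), `mass` (vertex
#'   dual areas).
#' @export
assemble_laplacian <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  n <- nrow(V)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cot_cap <- 1 / tan(1e-3)
  warned <- FALSE
  for (c0 in 1:3) {
    j <- F[, c0]; k1 <- F[, c0 %% 3 + 1]; k2 <- F[, (c0 + 1) %% 3 + 1]
    u <- V[k1, , drop = FALSE] - V[j, , drop = FALSE]
    v <- V[k2, , drop = FALSE] - V[j, , drop = FALSE]
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    s <- sqrt(rowSums(cr^2))
    ct <- rowSums(u * v) / pmax(s, 1e-300)
    if (any(abs(ct) > cot_cap)) {
      if (!warned) { warning("near-degenerate triangle: cotangent weights clamped"); warned <- TRUE }
      ct <- pmin(pmax(ct, -cot_cap), cot_cap)
    }
    ii <- c(ii, k1, k2); jj <- c(jj, k2, k1); xx <- c(xx, ct / 2, ct / 2)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  W <- W - Matrix::Diagonal(n, Matrix::rowSums(W))
  g <- compute_geometry(mesh)
  list(W = W, mass = g$vertex_dual_area)
}

#' Surface average of a vertex field
#'
#' Lumped-mass quadrature: `abar = sum(m_i a_i) / sum(m_i)` with `m_i` the
#' barycentric dual areas.
#'
#' @param mesh a `surface_mesh`.
#' @param a per-vertex values.
#' @param mass optional precomputed vertex masses.
#' @return scalar average.
#' @export
surface_average <- function(mesh, a, mass = NULL) {
  if (is.null(mass)) mass <- compute_geometry(mesh)$vertex_dual_area
  sum(mass * a) / sum(mass)
}

# face-based cue averaged to vertices with barycentric (A/3) weights
cue_to_vertices <- function(mesh, u_face, geom = compute_geometry(mesh)) {
  n <- nrow(mesh$V)
  num <- numeric(n); den <- numeric(n)
  w <- geom$face_area / 3
  grp <- c(mesh$F[, 1], mesh$F[, 2], mesh$F[, 3])
  acc <- rowsum(cbind(rep(w * u_face, 3), rep(w, 3)), grp)
  idx <- as.integer(rownames(acc))
  num[idx] <- acc[, 1]; den[idx] <- acc[, 2]
  num / den
}

# Hill response 1/(1 + x^-q), computed stably via exp(-q log x) with x
# clamped >= 1e-12 (umin > 0 is the supported configuration).
hill_pos <- function(x, q) {
  x <- pmax(x, 1e-12)
  1 / (1 + exp(-q * log(x)))
}

# Precompute the implicit-diffusion factorisation and per-vertex cue for a
# fixed mesh + cue (reused across quasi-steady iterations).
rd_operator <- function(mesh, cue, params) {
  lap <- assemble_laplacian(mesh)
  geom <- compute_geometry(mesh)
  uv <- cue_to_vertices(mesh, cue$u, geom)
  pv <- hill_pos(params$beta * uv, params$q)
  n <- nrow(mesh$V)
  M <- Matrix::Diagonal(n, lap$mass)
  A <- M - params$dt_chem * params$Dc * lap$W   # SPD since -W is PSD
  list(chol = Matrix::Cholesky(methods::as(A, "symmetricMatrix")),
       mass = lap$mass, pv = pv, W = lap$W)
}

#' One IMEX step of the reaction-diffusion system
#'
#' Operator-split step for the activator: the production terms (cue-driven
#' activation and self-enhancement) are applied explicitly, diffusion by a
#' backward-Euler solve with the cotangent Laplacian, and the linear
#' inactivation terms (`k2 + k3 b`) by their exact exponential decay
#' factor. Every substep preserves non-negativity, so the scheme is
#' unconditionally stable and never needs clipping; the `clipped` attribute
#' is retained for interface compatibility and counts any negative values
#' produced by round-off. The global-inhibitor ODE is advanced with a
#' multiplicatively clamped explicit step using the updated surface
#' average (the fixed point `abar = kss` is unaffected by the clamp).
#'
#' @param mesh a `surface_mesh`.
#' @param state a `chemical_state`.
#' @param cue a `cue_field` (see [cue_field()]).
#' @param params a `signaling_params`.
#' @param dt_chem chemical time step (defaults to `params$dt_chem`).
#' @param op optional precomputed operator from an earlier call (internal
#'   reuse across quasi-steady iterations).
#' @return updated `chemical_state` with attributes `max_da_dt` and
#'   `clipped`.
#' @export
rd_step <- function(mesh, state, cue, params, dt_chem = params$dt_chem,
                    op = NULL) {
  if (is.null(op)) op <- rd_operator(mesh, cue, params)
  a <- state$a; b <- state$b
  production <- params$k0 * op$pv +
    params$k1 * hill_pos(params$gamma * op$pv * a, params$h)
  rhs <- op$mass * (a + dt_chem * production)
  a_new <- as.numeric(Matrix::solve(op$chol, rhs, system = "A"))
  a_new <- a_new * exp(-dt_chem * (params$k2 + params$k3 * b))
  clipped <- sum(a_new < 0)
  a_new[a_new < 0] <- 0
  abar <- sum(op$mass * a_new) / sum(op$mass)
  # multiplicative clamp keeps the integral-control ODE stable far from
  # equilibrium (the fixed point abar = kss is unaffected)
  fac <- min(2, max(0.5, 1 + dt_chem * params$k4 * (abar - params$kss)))
  b_new <- b * fac
  if (b_new <= 0 || !is.finite(b_new)) b_new <- .Machine$double.xmin
  out <- chemical_state(a_new, b_new)
  attr(out, "max_da_dt") <- max(abs(a_new - a)) / dt_chem
  attr(out, "clipped") <- clipped
  out
}

#' Solve the reaction-diffusion system to quasi-steady state
#'
#' Iterates [rd_step()] on the fixed current geometry until both the
#' activator field is stationary (`max |da|/dt < tol`) and the surface
#' average has reached the homeostatic set point (`|abar - kss| < tol`),
#' or `max_iters` is exceeded (warning; best state returned flagged
#' non-converged). The implicit-diffusion operator is factorised once and
#' reused.
#'
#' @param mesh a `surface_mesh`.
#' @param state initial `chemical_state`.
#' @param cue a `cue_field`.
#' @param params a `signaling_params`.
#' @param tol convergence tolerance.
#' @param max_iters iteration cap.
#' @return converged `chemical_state` with attributes `iterations`,
#'   `converged`, `abar`.
#' @export
solve_quasi_steady <- function(mesh, state, cue, params, tol = 1e-3,
                               max_iters = 2000) {
  stopifnot(tol > 0)
  op <- rd_operator(mesh, cue, params)
  it <- 0L
  converged <- FALSE
  while (it < max_iters) {
    state <- rd_step(mesh, state, cue, params, op = op)
    it <- it + 1L
    abar <- sum(op$mass * state$a) / sum(op$mass)
    if (attr(state, "max_da_dt") < tol && abs(abar - params$kss) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("quasi-steady solve did not converge in %d iterations", it))
  attr(state, "iterations") <- it
  attr(state, "converged") <- converged
  attr(state, "abar") <- sum(op$mass * state$a) / sum(op$mass)
  state
}

#' Transfer the chemical state across a remodeling step
#'
#' Edge swaps leave the vertex set unchanged, so the field is carried over
#' as is. Each split inserts one vertex, which receives the mean of its
#' parent edge's endpoint values (recorded in the mesh provenance). The
#' global inhibitor is unchanged.
#'
#' @param old_mesh mesh before remodeling.
#' @param state `chemical_state` on `old_mesh`.
#' @param new_mesh mesh after remodeling, carrying a `provenance` attribute
#'   when vertices were added.
#' @return `chemical_state` on `new_mesh`.
#' @export
transfer_state_after_remodel <- function(old_mesh, state, new_mesh) {
  n_old <- nrow(old_mesh$V); n_new <- nrow(new_mesh$V)
  if (n_new == n_old) return(chemical_state(state$a, state$b))
  prov <- attr(new_mesh, "provenance")
  if (is.null(prov))
    stop("mesh gained vertices but carries no remodeling provenance")
  a <- state$a
  for (p in prov) {
    if (p$new_vertex != length(a) + 1L)
      stop("provenance out of order with vertex numbering")
    a <- c(a, mean(a[p$parents]))
  }
  if (length(a) != n_new) stop("provenance does not account for all new vertices")
  chemical_state(a, state$b)
}
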