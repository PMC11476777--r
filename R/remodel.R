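#' Growth policy for periodic surface-material insertion
#'
#' New cell surface material is delivered periodically at a constant rate:
#' each growth event performs a fixed number of triangle-pair splits inside
#' the chemically eligible region, which yields linear growth of the bud
#' surface area by construction. After each event a scheduled number of
#' Metropolis edge-swap attempts relaxes the network.
#'
#' @param threshold_fraction fraction of the maximum bud concentration
#'   gating insertion (a face is eligible when its mean vertex
#'   concentration is at least this fraction of the bud maximum).
#' @param insertions_per_event number of triangle-pair splits per growth
#'   event.
#' @param rest_growth_factor multiplier (> 1) applied to the current
#'   geometry when assigning rest quantities of newly created elements, so
#'   every event raises the total rest area.
#' @param es_schedule edge-swap schedule: a single number (constant), a
#'   function of the frame index, or a list `list(frames = c(...), steps =
#'   c(...))` giving a piecewise-constant schedule (step `steps[i]` applies
#'   from frame `frames[i]` on).
#' @param kT Metropolis temperature for swap acceptance.
#' @param swap_domain `"all"` to propose swaps over the entire surface,
#'   `"bud"` to restrict them to the bud.
#' @param normal_offset small outward offset applied to newly inserted
#'   vertices (fraction of local edge length) to avoid coplanar degeneracy.
#' @param min_split_frac minimum feature size: only edges whose current
#'   length is at least this fraction of the mesh-wide mean rest length are
#'   candidates for splitting, preventing unbounded local refinement of a
#'   small growth region.
#' @param rest_dihedral rest angle of newly inserted hinges: `"current"`
#'   (default; deposited material adopts the local curvature, so grown
#'   shapes are remembered) or `"flat"` (new wall carries no intrinsic
#'   curvature, giving bending a drive to relax highly curved grown
#'   regions — used by the relaxation-time experiments).
#' @return an object of class `growth_policy`.
#' @export
growth_policy <- function(threshold_fraction = 0.8, insertions_per_event = 4,
                          rest_growth_factor = 1.4, es_schedule = 25,
                          kT = 0.05, swap_domain = c("all", "bud"),
                          normal_offset = 0.1, min_split_frac = 0.4,
                          rest_dihedral = c("current", "flat")) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1,
            insertions_per_event >= 1, rest_growth_factor > 1, kT >= 0,
            min_split_frac >= 0)
  structure(list(threshold_fraction = threshold_fraction,
                 insertions_per_event = as.integer(insertions_per_event),
                 rest_growth_factor = rest_growth_factor,
                 es_schedule = es_schedule, kT = kT,
                 swap_domain = match.arg(swap_domain),
                 normal_offset = normal_offset,
                 min_split_frac = min_split_frac,
                 rest_dihedral = match.arg(rest_dihedral)),
            class = "growth_policy")
}

#' Evaluate an edge-swap schedule at a frame
#'
#' @param es_schedule see [growth_policy()].
#' @param frame frame index (1-based).
#' @return integer number of swap attempts.
#' @export
es_steps_at <- function(es_schedule, frame) {
  if (is.function(es_schedule)) return(as.integer(es_schedule(frame)))
  if (is.list(es_schedule)) {
    i <- findInterval(frame, es_schedule$frames)
    if (i < 1) i <- 1
    return(as.integer(es_schedule$steps[i]))
  }
  as.integer(es_schedule)
}

# edge row index for vertex pair (a, b); 0 if absent
find_edge <- function(mesh, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  k <- which(mesh$edges[, 1] == lo & mesh$edges[, 2] == hi)
  if (length(k) == 0) 0L else k[1]
}

#' Split a pair of adjacent triangles into four
#'
#' Inserts a new vertex at the midpoint of the given edge (with an optional
#' small outward normal offset) and replaces the two incident triangles by
#' four, turning the two-triangles-four-nodes configuration into a
#' four-triangles-five-nodes one. Rest lengths and rest areas of the new
#' elements are assigned from the current geometry scaled by
#' `rest_growth_factor`, which is how each insertion adds surface material;
#' rest dihedrals of the affected hinges are reset to their current angles.
#' Region and eligibility labels are inherited from the parent faces.
#'
#' @param mesh a `surface_mesh`.
#' @param edge edge row index to split (must not be a septin-ring edge).
#' @param rest_growth_factor rest-quantity multiplier (> 1 grows material).
#' @param normal_offset outward offset of the new vertex as a fraction of
#'   the split edge length.
#' @param rest_dihedral rest angle assigned to the hinges of the newly
#'   inserted material: `"flat"` (0, new wall has no intrinsic curvature,
#'   so bending drives highly curved grown regions to relax) or
#'   `"current"` (frozen at the post-split geometry).
#' @return the updated `surface_mesh`, with an attribute `provenance`
#'   recording `new_vertex` and `parents` for chemical-state transfer.
#' @export
split_pair <- function(mesh, edge, rest_growth_factor = 1.4,
                       normal_offset = 0,
                       rest_dihedral = c("current", "flat")) {
  rest_dihedral <- match.arg(rest_dihedral)
  k <- edge
  stopifnot(k >= 1, k <= nrow(mesh$edges))
  if (mesh$septin[k])
    stop("refusing to split a septin-ring edge (ring topology must be preserved)")
  if (mesh$edge_faces[k, 2] == 0L)
    stop("cannot split a boundary edge: the edge must have two incident faces")
  v0 <- mesh$edges[k, 1]; v1 <- mesh$edges[k, 2]
  f1 <- mesh$edge_faces[k, 1]; f2 <- mesh$edge_faces[k, 2]
  g <- compute_geometry(mesh)
  mid <- (mesh$V[v0, ] + mesh$V[v1, ]) / 2
  if (normal_offset != 0) {
    nh <- (g$face_normal[f1, ] + g$face_normal[f2, ])
    nh <- nh / sqrt(sum(nh^2))
    mid <- mid + normal_offset * g$edge_length[k] * nh
  }
  q1 <- mesh$edge_opp[k, 1]; q2 <- mesh$edge_opp[k, 2]
  w <- nrow(mesh$V) + 1L
  Vn <- rbind(mesh$V, mid)
  Fn <- mesh$F
  Fn[f1, ] <- c(v0, w, q1)
  Fn[f2, ] <- c(v1, w, q2)
  Fn <- rbind(Fn, c(w, v1, q1), c(w, v0, q2))
  storage.mode(Fn) <- "integer"
  region <- c(mesh$region, mesh$region[f1], mesh$region[f2])
  elig_old <- attr(mesh, "eligible")
  out <- rebuild_after_edit(mesh, Vn, Fn, region)
  # rest state: carried over for surviving edges inside rebuild_after_edit;
  # now assign the new elements from current geometry x growth factor
  gn <- compute_geometry(out)
  newe <- which(is.na(out$L0))
  out$L0[newe] <- gn$edge_length[newe] * rest_growth_factor
  nf <- nrow(Fn)
  out$A0[c(f1, f2, nf - 1L, nf)] <- gn$face_area[c(f1, f2, nf - 1L, nf)] * rest_growth_factor
  # hinges whose incident faces changed: old material keeps its shape
  # (rest dihedral reset to the current angle); the new material's own
  # hinges are born flat unless "current" is requested
  touched <- which(out$edge_faces[, 1] %in% c(f1, f2, nf - 1L, nf) |
                   out$edge_faces[, 2] %in% c(f1, f2, nf - 1L, nf))
  out$theta0[touched] <- gn$dihedral_angle[touched]
  if (rest_dihedral == "flat") out$theta0[newe] <- 0
  if (!is.null(elig_old))
    attr(out, "eligible") <- c(elig_old, elig_old[f1], elig_old[f2])
  attr(out, "provenance") <- list(list(new_vertex = w, parents = c(v0, v1)))
  out
}

# Rebuild the edge table after a face-list edit, carrying over rest lengths,
# rest dihedrals and septin flags of surviving edges by vertex-pair key.
# New edges get NA rest quantities (caller assigns them).
rebuild_after_edit <- function(mesh, Vn, Fn, region) {
  et <- build_edge_table(Fn)
  nmax <- nrow(Vn) + 1
  key_new <- as.numeric(et$edges[, 1]) * nmax + et$edges[, 2]
  key_old <- as.numeric(mesh$edges[, 1]) * nmax + mesh$edges[, 2]
  idx <- match(key_new, key_old)
  out <- mesh
  dimnames(Vn) <- NULL
  out$V <- Vn; out$F <- Fn
  out$edges <- et$edges; out$edge_faces <- et$edge_faces; out$edge_opp <- et$edge_opp
  out$L0 <- ifelse(is.na(idx), NA_real_, mesh$L0[idx])
  out$theta0 <- ifelse(is.na(idx), NA_real_, mesh$theta0[idx])
  out$septin <- ifelse(is.na(idx), FALSE, mesh$septin[idx])
  out$A0 <- c(mesh$A0, rep(NA_real_, nrow(Fn) - nrow(mesh$F)))
  out$region <- as.integer(region)
  for (a in c("provenance", "eligible")) attr(out, a) <- NULL
  out
}

#' Faces eligible for material insertion
#'
#' Bud faces whose mean vertex concentration of active Cdc42 is at least
#' `threshold_fraction` times the maximum vertex concentration on the bud
#' (the polarization region). Mother faces are never eligible: new surface
#' material is only added within the bud.
#'
#' @param mesh a `surface_mesh`.
#' @param a per-vertex concentration vector.
#' @param threshold_fraction gating fraction (default 0.8).
#' @return integer vector of eligible face indices (possibly empty).
#' @export
eligible_faces <- function(mesh, a, threshold_fraction = 0.8) {
  stopifnot(length(a) == nrow(mesh$V))
  bud <- which(mesh$region == REGION_BUD)
  if (length(bud) == 0) stop("mesh has no bud faces")
  bud_verts <- unique(as.vector(mesh$F[bud, ]))
  cmax <- max(a[bud_verts])
  if (cmax <= 0) return(integer(0))
  fmean <- (a[mesh$F[bud, 1]] + a[mesh$F[bud, 2]] + a[mesh$F[bud, 3]]) / 3
  bud[fmean >= threshold_fraction * cmax]
}

#' One growth event: insert material into the eligible region
#'
#' Splits `insertions_per_event` edges chosen uniformly at random among the
#' interior edges of the given face region (edges both of whose incident
#' faces belong to the region, excluding septin-ring edges). If the region
#' has fewer interior edges than requested, as many as available are split
#' and the shortfall is reported via the `shortfall` attribute. Newly
#' created faces belong to the region and may be chosen by subsequent
#' insertions within the same event. Uses R's RNG stream (seed for
#' reproducibility).
#'
#' @param mesh a `surface_mesh`.
#' @param region integer vector of face indices (non-empty).
#' @param policy a `growth_policy`.
#' @return the grown `surface_mesh` with accumulated `provenance`.
#' @export
growth_event <- function(mesh, region, policy) {
  stopifnot(length(region) > 0)
  elig <- rep(FALSE, nrow(mesh$F))
  elig[region] <- TRUE
  attr(mesh, "eligible") <- elig
  prov <- list()
  done <- 0L
  min_len <- policy$min_split_frac * mean(mesh$L0)
  for (i in seq_len(policy$insertions_per_event)) {
    el <- attr(mesh, "eligible")
    cand <- which(el[mesh$edge_faces[, 1]] & el[mesh$edge_faces[, 2]] &
                  !mesh$septin)
    if (length(cand) > 0 && min_len > 0) {
      d <- mesh$V[mesh$edges[cand, 2], , drop = FALSE] -
           mesh$V[mesh$edges[cand, 1], , drop = FALSE]
      cand <- cand[sqrt(rowSums(d^2)) >= min_len]
    }
    if (length(cand) == 0) break
    k <- cand[sample.int(length(cand), 1)]
    mesh <- split_pair(mesh, k, policy$rest_growth_factor,
                       policy$normal_offset, policy$rest_dihedral)
    prov <- c(prov, attr(mesh, "provenance"))
    done <- done + 1L
  }
  attr(mesh, "provenance") <- prov
  attr(mesh, "shortfall") <- policy$insertions_per_event - done
  mesh
}

# Metropolis acceptance rule; kT = 0 is the greedy (descent-only) limit.
metropolis_accept <- function(dE, kT) {
  if (dE <= 0) return(TRUE)
  if (kT <= 0) return(FALSE)
  stats::runif(1) < exp(-dE / kT)
}

# Local energy of the elements touched by a flip of edge k: the central
# hinge + spring, the four boundary hinges, the two incident faces, and the
# two Morse pair terms whose adjacency status the flip changes.
flip_local_energy <- function(V, faces, hinges, springs, A0f, params,
                              morse_pairs) {
  E <- 0
  for (i in seq_along(springs)) {
    s <- springs[[i]]
    L <- sqrt(sum((V[s$j, ] - V[s$i, ])^2))
    E <- E + 0.5 * s$ks * (L - s$L0)^2
  }
  for (f in seq_len(nrow(faces))) {
    p <- V[faces[f, ], , drop = FALSE]
    N <- crossp(p[2, ] - p[1, ], p[3, ] - p[1, ])
    A <- sqrt(sum(N^2)) / 2
    E <- E + 0.5 * params$ka / A0f[f] * (A - A0f[f])^2
  }
  for (h in hinges) {
    n1 <- face_unit_normal(V, h$fa)
    n2 <- face_unit_normal(V, h$fb)
    th <- atan2(sqrt(sum(crossp(n1, n2)^2)), sum(n1 * n2))
    E <- E + h$kb * (1 - cos(th - h$theta0))
  }
  for (mp in morse_pairs) {
    L <- sqrt(sum((V[mp[1], ] - V[mp[2], ])^2))
    if (L <= params$Lm)
      E <- E + params$Dm * (1 - exp(-params$am * (L - params$Lm)))^2
  }
  E
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
face_unit_normal <- function(V, f) {
  N <- crossp(V[f[2], ] - V[f[1], ], V[f[3], ] - V[f[1], ])
  nn <- sqrt(sum(N^2))
  if (nn > 0) N / nn else c(0, 0, 0)
}

#' Attempt one Metropolis edge flip
#'
#' Proposes flipping the shared edge of the two triangles incident to
#' `edge`: the central edge is replaced by the other diagonal of the
#' quadrilateral. The move is rejected outright when illegal (septin-ring
#' edge, duplicate edge would be created, a vertex would drop below valence
#' 3, or a degenerate face would result); otherwise it is accepted with
#' probability `min(1, exp(-dE/kT))`, where `dE` is the change in local
#' energy including the rest-state reassignment of the flipped edge (rest
#' length = mean of the four boundary rest lengths; face rest areas
#' rescaled to preserve their summed rest area; rest dihedral of the new
#' hinge = its current angle).
#'
#' @param mesh a `surface_mesh`.
#' @param params a `mech_params`.
#' @param kT Metropolis temperature.
#' @param edge edge row index to attempt; if `NULL`, drawn uniformly among
#'   non-septin edges.
#' @return the (possibly unchanged) `surface_mesh` with attributes
#'   `accepted` (logical) and `illegal` (logical).
#' @export
edge_swap_step <- function(mesh, params, kT, edge = NULL) {
  if (is.null(edge)) {
    cand <- which(!mesh$septin)
    edge <- cand[sample.int(length(cand), 1)]
  }
  k <- edge
  rej <- function(m) { attr(m, "accepted") <- FALSE; attr(m, "illegal") <- TRUE; m }
  if (mesh$septin[k] || mesh$edge_faces[k, 2] == 0L) return(rej(mesh))
  v0 <- mesh$edges[k, 1]; v1 <- mesh$edges[k, 2]
  q1 <- mesh$edge_opp[k, 1]; q2 <- mesh$edge_opp[k, 2]
  f1 <- mesh$edge_faces[k, 1]; f2 <- mesh$edge_faces[k, 2]
  if (q1 == q2) return(rej(mesh))
  if (find_edge(mesh, q1, q2) > 0) return(rej(mesh))
  val <- tabulate(mesh$edges, nbins = nrow(mesh$V))
  if (val[v0] <= 3 || val[v1] <= 3) return(rej(mesh))
  # proposed faces: A = (q1, v0, q2), B = (q2, v1, q1)
  fA <- c(q1, v0, q2); fB <- c(q2, v1, q1)
  aA <- 0.5 * sqrt(sum(crossp(mesh$V[fA[2], ] - mesh$V[fA[1], ],
                              mesh$V[fA[3], ] - mesh$V[fA[1], ])^2))
  aB <- 0.5 * sqrt(sum(crossp(mesh$V[fB[2], ] - mesh$V[fB[1], ],
                              mesh$V[fB[3], ] - mesh$V[fB[1], ])^2))
  if (aA <= 1e-12 || aB <= 1e-12) return(rej(mesh))
  co_reg <- if (mesh$region[f1] == REGION_BUD) "bud" else "mother"
  ks_c <- params$ks[[co_reg]]; kb_c <- params$kb[[co_reg]]
  b_edges <- c(find_edge(mesh, v0, q1), find_edge(mesh, v1, q1),
               find_edge(mesh, v1, q2), find_edge(mesh, v0, q2))
  hinge_of <- function(ke) {
    list(fa = mesh$F[mesh$edge_faces[ke, 1], ],
         fb = mesh$F[mesh$edge_faces[ke, 2], ],
         kb = elastic_kb_edge(mesh, ke, params),
         theta0 = mesh$theta0[ke])
  }
  # ---- energy before -----------------------------------------------------
  hinges_before <- lapply(c(k, b_edges), hinge_of)
  springs_before <- list(list(i = v0, j = v1, ks = ks_c, L0 = mesh$L0[k]))
  E_before <- flip_local_energy(mesh$V, mesh$F[c(f1, f2), , drop = FALSE],
                                hinges_before, springs_before,
                                mesh$A0[c(f1, f2)], params,
                                morse_pairs = list(c(q1, q2)))
  # ---- energy after (with rest reassignment) -----------------------------
  L0_new <- mean(mesh$L0[b_edges])
  A0_sum <- sum(mesh$A0[c(f1, f2)])
  A0_new <- c(aA, aB) / (aA + aB) * A0_sum
  Fprop <- rbind(fA, fB)
  # boundary hinges after the flip: replace the old incident face by the
  # new one on the flipped side
  hinge_after <- function(ke) {
    h <- hinge_of(ke)
    repl <- function(f) {
      sf <- sort(f)
      if (identical(sf, sort(mesh$F[f1, ])) || identical(sf, sort(mesh$F[f2, ]))) {
        ve <- mesh$edges[ke, ]
        if (all(ve %in% fA)) fA else fB
      } else f
    }
    h$fa <- repl(h$fa); h$fb <- repl(h$fb)
    h
  }
  nA <- face_unit_normal(mesh$V, fA); nB <- face_unit_normal(mesh$V, fB)
  th_new <- atan2(sqrt(sum(crossp(nA, nB)^2)), sum(nA * nB))
  hinges_after <- c(list(list(fa = fA, fb = fB, kb = kb_c, theta0 = th_new)),
                    lapply(b_edges, hinge_after))
  springs_after <- list(list(i = q1, j = q2, ks = ks_c, L0 = L0_new))
  E_after <- flip_local_energy(mesh$V, Fprop, hinges_after, springs_after,
                               A0_new, params,
                               morse_pairs = list(c(v0, v1)))
  dE <- E_after - E_before
  if (!metropolis_accept(dE, kT)) {
    attr(mesh, "accepted") <- FALSE; attr(mesh, "illegal") <- FALSE
    attr(mesh, "dE") <- dE
    return(mesh)
  }
  # ---- apply the flip in place -------------------------------------------
  mesh$F[f1, ] <- fA
  mesh$F[f2, ] <- fB
  lo <- min(q1, q2); hi <- max(q1, q2)
  mesh$edges[k, ] <- c(lo, hi)
  if (q1 < q2) {  # face traversing q1 -> q2 is B (slot f2)
    mesh$edge_faces[k, ] <- c(f2, f1)
    mesh$edge_opp[k, ] <- c(v1, v0)
  } else {        # face traversing q2 -> q1 is A (slot f1)
    mesh$edge_faces[k, ] <- c(f1, f2)
    mesh$edge_opp[k, ] <- c(v0, v1)
  }
  mesh$L0[k] <- L0_new
  mesh$theta0[k] <- th_new
  mesh$septin[k] <- FALSE
  mesh$A0[c(f1, f2)] <- A0_new
  # boundary edge bookkeeping: the untouched outer face keeps its traversal
  # direction, so the new inner face occupies the same slot the old inner
  # face (f1 or f2) held; only the face id and opposite vertex change.
  for (ke in b_edges) {
    ve <- mesh$edges[ke, ]
    inA <- all(ve %in% fA)
    nf_id <- if (inA) f1 else f2
    nf <- if (inA) fA else fB
    s <- which(mesh$edge_faces[ke, ] %in% c(f1, f2))[1]
    mesh$edge_faces[ke, s] <- nf_id
    mesh$edge_opp[ke, s] <- setdiff(nf, ve)
  }
  attr(mesh, "accepted") <- TRUE
  attr(mesh, "illegal") <- FALSE
  attr(mesh, "dE") <- dE
  mesh
}

# bending coefficient of one hinge (region-dependent)
elastic_kb_edge <- function(mesh, ke, params) {
  r1 <- mesh$region[mesh$edge_faces[ke, 1]]
  r2 <- mesh$region[mesh$edge_faces[ke, 2]]
  if (r1 == REGION_BUD && r2 == REGION_BUD) params$kb[["bud"]] else params$kb[["mother"]]
}

#' Run a batch of Metropolis edge-swap attempts
#'
#' Performs `n_steps` flip attempts at uniformly random candidate edges
#' (the whole surface or the bud only, per `swap_domain`), each accepted by
#' the Metropolis rule at temperature `kT`. Vertex, edge and face counts
#' are invariant under any number of swaps.
#'
#' With `relax_per_swap > 0`, each attempt is followed by that many
#' overdamped Euler steps of the mechanics, so the swap count acts as a
#' true relaxation clock: scheduling more swap attempts per growth event
#' gives the surface proportionally more time to rearrange *and* to move,
#' which is what distinguishes the near-equilibrium (spherical) from the
#' nonequilibrium (tubular) growth regimes.
#'
#' @param mesh a `surface_mesh`.
#' @param n_steps number of attempts (>= 0).
#' @param params a `mech_params`.
#' @param kT Metropolis temperature.
#' @param swap_domain `"all"` or `"bud"`.
#' @param relax_per_swap mechanical Euler steps interleaved after each
#'   attempt (0 = pure connectivity moves).
#' @param relax_force_tol force tolerance for the interleaved relaxation.
#' @param dmax per-step displacement cap of the interleaved relaxation.
#' @return the `surface_mesh` with attributes `accepted_swaps` and
#'   `illegal_swaps`.
#' @export
run_swaps <- function(mesh, n_steps, params, kT, swap_domain = "all",
                      relax_per_swap = 0, relax_force_tol = 1e-3,
                      dmax = 0.01) {
  stopifnot(n_steps >= 0)
  acc <- 0L; ill <- 0L
  co <- if (relax_per_swap > 0) elastic_coeffs(mesh, params) else NULL
  for (s in seq_len(n_steps)) {
    if (swap_domain == "bud") {
      bud_f <- mesh$region == REGION_BUD
      cand <- which(bud_f[mesh$edge_faces[, 1]] & bud_f[mesh$edge_faces[, 2]] &
                    !mesh$septin)
    } else {
      cand <- which(!mesh$septin)
    }
    if (length(cand) == 0) break
    k <- cand[sample.int(length(cand), 1)]
    mesh <- edge_swap_step(mesh, params, kT, edge = k)
    if (isTRUE(attr(mesh, "accepted"))) acc <- acc + 1L
    if (isTRUE(attr(mesh, "illegal"))) ill <- ill + 1L
    if (relax_per_swap > 0) {
      # flips change neither regions nor the septin set, so the
      # coefficient vectors stay valid across the whole batch
      res <- .bm_relax(mesh$V, mesh$F, mesh$edges, mesh$edge_faces,
                       mesh$edge_opp, mesh$L0, mesh$theta0, mesh$A0,
                       co$ks_edge, co$kb_edge, co$ka_face,
                       params$Dm, params$am, params$Lm, params$P,
                       params$c, params$dt, as.integer(relax_per_swap),
                       relax_force_tol, dmax)
      if (res$finite) mesh$V <- res$V
    }
  }
  attr(mesh, "accepted_swaps") <- acc
  attr(mesh, "illegal_swaps") <- ill
  attr(mesh, "accepted") <- NULL
  attr(mesh, "illegal") <- NULL
  mesh
}
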