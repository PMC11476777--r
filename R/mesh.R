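#' @useDynLib budmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

# Region codes used in the face label vector.
REGION_MOTHER <- 0L
REGION_BUD <- 1L

#' Construct a surface mesh from vertices and faces
#'
#' Builds the closed, oriented triangulated surface used throughout the
#' package: the edge table with incident faces and opposite (hinge) vertices
#' is derived from the face list, and the rest state (spring rest lengths
#' `L0`, rest dihedral angles `theta0`, rest face areas `A0`) is initialised
#' from the current geometry, i.e. the mesh as given is stress free.
#'
#' @param V numeric matrix (n x 3) of vertex positions.
#' @param F integer matrix (m x 3) of vertex index triples with consistent
#'   outward winding.
#' @param region optional integer vector (length m) of face labels,
#'   0 = mother, 1 = bud. Defaults to all mother.
#' @return An object of class `surface_mesh`: a list with components
#'   `V`, `F`, `edges`, `edge_faces`, `edge_opp`, `L0`, `theta0`, `A0`,
#'   `region`, `septin` (logical per edge), and `bud_axis`.
#' @export
surface_mesh <- function(V, F, region = NULL) {
  V <- as.matrix(V)
  storage.mode(V) <- "double"
  F <- as.matrix(F)
  storage.mode(F) <- "integer"
  dimnames(V) <- NULL
  dimnames(F) <- NULL
  stopifnot(ncol(V) == 3, ncol(F) == 3)
  if (min(F) < 1L || max(F) > nrow(V))
    stop("face indices out of range")
  et <- build_edge_table(F)
  mesh <- structure(list(
    V = V, F = F,
    edges = et$edges, edge_faces = et$edge_faces, edge_opp = et$edge_opp,
    L0 = numeric(nrow(et$edges)), theta0 = numeric(nrow(et$edges)),
    A0 = numeric(nrow(F)),
    region = if (is.null(region)) rep(REGION_MOTHER, nrow(F)) else as.integer(region),
    septin = rep(FALSE, nrow(et$edges)),
    bud_axis = c(0, 0, 1)
  ), class = "surface_mesh")
  reset_rest_state(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d edges, %d faces (chi = %d)\n",
              nrow(x$V), nrow(x$edges), nrow(x$F),
              nrow(x$V) - nrow(x$edges) + nrow(x$F)))
  cat(sprintf("  bud faces: %d, septin edges: %d\n",
              sum(x$region == REGION_BUD), sum(x$septin)))
  invisible(x)
}

# Edge table from an oriented face list. For an interior edge row k with
# endpoints (a, b), a < b, edge_faces[k, 1] is the face traversing the edge
# as a -> b and edge_faces[k, 2] the face traversing b -> a; edge_opp holds
# the third vertex of each of those faces. Consistent winding on a closed
# surface guarantees each undirected edge occurs exactly once in each
# direction. Boundary edges (open patches) get 0 in the second slot.
build_edge_table <- function(F) {
  m <- nrow(F)
  a <- c(F[, 1], F[, 2], F[, 3])
  b <- c(F[, 2], F[, 3], F[, 1])
  face <- rep.int(seq_len(m), 3L)
  opp <- c(F[, 3], F[, 1], F[, 2])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- as.numeric(lo) * (max(hi) + 1) + hi
  cnt <- table(key)
  if (any(cnt > 2))
    stop("mesh is not 2-manifold: an edge has more than 2 incident faces")
  ord <- order(key)
  kord <- key[ord]
  is_pair <- kord %in% names(cnt)[cnt == 2]
  # paired (interior) half-edges
  pi1 <- ord[is_pair][c(TRUE, FALSE)]
  pi2 <- ord[is_pair][c(FALSE, TRUE)]
  if (length(pi1)) {
    fwd1 <- a[pi1] < b[pi1]
    if (any(fwd1 == (a[pi2] < b[pi2])))
      stop("inconsistent winding: an edge is traversed twice in the same direction")
    first <- ifelse(fwd1, pi1, pi2)   # half-edge running lo -> hi
    second <- ifelse(fwd1, pi2, pi1)  # half-edge running hi -> lo
  } else {
    first <- integer(0); second <- integer(0)
  }
  bnd <- ord[!is_pair]
  zeros <- rep.int(0L, length(bnd))
  list(
    edges = rbind(cbind(lo[first], hi[first]), cbind(lo[bnd], hi[bnd])),
    edge_faces = rbind(cbind(face[first], face[second]),
                       cbind(face[bnd], zeros)),
    edge_opp = rbind(cbind(opp[first], opp[second]), cbind(opp[bnd], zeros)),
    n_boundary = length(bnd)
  )
}

# Re-initialise all rest quantities from the current geometry.
reset_rest_state <- function(mesh) {
  g <- compute_geometry(mesh)
  mesh$L0 <- g$edge_length
  mesh$theta0 <- g$dihedral_angle
  mesh$A0 <- g$face_area
  mesh
}

#' Compute instantaneous geometry of a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @return A list (`geometry_cache`) with `face_area`, `face_normal`
#'   (outward unit normals, m x 3), `dihedral_angle` (unsigned angle between
#'   the unit normals of the two faces incident to each edge, radians),
#'   `edge_length`, `vertex_dual_area` (barycentric lumped areas, one third
#'   of each incident face area), and `total_area`.
#' @export
compute_geometry <- function(mesh) {
  V <- mesh$V; F <- mesh$F
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  N <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(N^2))
  area <- nrm / 2
  if (any(area <= 0 | !is.finite(area)))
    stop(sprintf("degenerate face(s): %s",
                 paste(which(area <= 0 | !is.finite(area)), collapse = ", ")))
  n_hat <- N / nrm
  d <- V[mesh$edges[, 2], , drop = FALSE] - V[mesh$edges[, 1], , drop = FALSE]
  elen <- sqrt(rowSums(d^2))
  interior <- mesh$edge_faces[, 2] > 0L
  n1 <- n_hat[mesh$edge_faces[, 1], , drop = FALSE]
  n2 <- n_hat[pmax(mesh$edge_faces[, 2], 1L), , drop = FALSE]
  cx <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
              n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
              n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
  theta <- atan2(sqrt(rowSums(cx^2)), rowSums(n1 * n2))
  theta[!interior] <- 0
  dual <- numeric(nrow(V))
  acc <- rowsum(rep(area / 3, 3), c(F[, 1], F[, 2], F[, 3]))
  dual[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(face_area = area, face_normal = n_hat,
                 dihedral_angle = theta, edge_length = elen,
                 vertex_dual_area = dual, total_area = sum(area)),
            class = "geometry_cache")
}

#' Build an icosphere fixture
#'
#' Recursively subdivided icosahedron projected onto a sphere, the standard
#' initial condition for the mother cell. Rest state is initialised to the
#' constructed geometry.
#'
#' @param subdivisions non-negative integer; each level quadruples the face
#'   count (V = 10 * 4^s + 2 vertices).
#' @param radius sphere radius (> 0), in simulation length units.
#' @return a `surface_mesh`.
#' @export
build_icosphere <- function(subdivisions = 3, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(F) <- "integer"
  for (s in seq_len(subdivisions)) {
    up <- subdivide_once(V, F)
    V <- up$V / sqrt(rowSums(up$V^2))
    F <- up$F
  }
  # enforce outward orientation via the signed volume
  vol <- sum(V[F[, 1], 1] * (V[F[, 2], 2] * V[F[, 3], 3] - V[F[, 2], 3] * V[F[, 3], 2]) +
             V[F[, 1], 2] * (V[F[, 2], 3] * V[F[, 3], 1] - V[F[, 2], 1] * V[F[, 3], 3]) +
             V[F[, 1], 3] * (V[F[, 2], 1] * V[F[, 3], 2] - V[F[, 2], 2] * V[F[, 3], 1])) / 6
  if (vol < 0) F <- F[, c(1, 3, 2)]
  surface_mesh(V * radius, F)
}

# One loop-style 1-to-4 subdivision (no smoothing), midpoints shared.
subdivide_once <- function(V, F) {
  n <- nrow(V)
  a <- c(F[, 1], F[, 2], F[, 3]); b <- c(F[, 2], F[, 3], F[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- as.numeric(lo) * (n + 1) + hi
  uk <- unique(key)
  mid_id <- n + match(key, uk)
  ul <- as.integer(uk %/% (n + 1)); uh <- as.integer(uk %% (n + 1))
  Vmid <- (V[ul, , drop = FALSE] + V[uh, , drop = FALSE]) / 2
  m <- nrow(F)
  m12 <- mid_id[1:m]; m23 <- mid_id[(m + 1):(2 * m)]; m31 <- mid_id[(2 * m + 1):(3 * m)]
  Fn <- rbind(cbind(F[, 1], m12, m31),
              cbind(F[, 2], m23, m12),
              cbind(F[, 3], m31, m23),
              cbind(m12, m23, m31))
  storage.mode(Fn) <- "integer"
  list(V = rbind(V, Vmid), F = Fn)
}

#' Designate a bud patch and septin ring
#'
#' Rotates the mesh so `axis` maps to +z, labels every face whose centroid
#' lies within `cap_angle` of the axis as bud, and marks the boundary edge
#' loop between bud and mother faces as the septin ring. The convention
#' throughout the package is that the bud axis is +z, so the bud tip is the
#' maximum-z vertex and the bottom of the mother cell is the minimum-z
#' vertex.
#'
#' @param mesh a `surface_mesh`.
#' @param axis direction of the future bud (need not be unit).
#' @param cap_angle angular radius of the geodesic cap, radians.
#' @return the relabelled (and rotated) `surface_mesh`.
#' @export
init_bud_patch <- function(mesh, axis = c(0, 0, 1), cap_angle = 0.5) {
  stopifnot(length(axis) == 3, cap_angle >= 0)
  R <- rotation_to_z(axis)
  mesh$V <- mesh$V %*% t(R)
  ctr <- colMeans(mesh$V)
  C <- (mesh$V[mesh$F[, 1], ] + mesh$V[mesh$F[, 2], ] + mesh$V[mesh$F[, 3], ]) / 3
  C <- sweep(C, 2, ctr)
  ang <- acos(pmin(1, pmax(-1, C[, 3] / sqrt(rowSums(C^2)))))
  bud <- ang <= cap_angle
  if (!any(bud) || all(bud))
    stop("cap_angle yields an empty or all-covering bud patch; adjust cap_angle")
  mesh$region <- ifelse(bud, REGION_BUD, REGION_MOTHER)
  r1 <- mesh$region[mesh$edge_faces[, 1]]
  r2 <- mesh$region[mesh$edge_faces[, 2]]
  mesh$septin <- r1 != r2
  mesh$bud_axis <- c(0, 0, 1)
  chk <- check_septin_ring(mesh)
  if (!chk$ok) stop("septin ring is not a single simple closed loop: ", chk$msg)
  # rest dihedrals are unchanged by the rigid rotation; recompute defensively
  mesh
}

# Rotation matrix mapping the given direction onto +z (Rodrigues).
rotation_to_z <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3], a[1] * z[2] - a[2] * z[1])
  c_ <- sum(a * z)
  if (sum(v^2) < 1e-30) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Septin ring integrity: every ring vertex must touch exactly two ring
# edges and the ring must be a single connected cycle.
check_septin_ring <- function(mesh) {
  re <- mesh$edges[mesh$septin, , drop = FALSE]
  if (nrow(re) == 0) return(list(ok = FALSE, msg = "no septin edges"))
  vs <- tabulate(c(re[, 1], re[, 2]), nbins = nrow(mesh$V))
  on <- which(vs > 0)
  if (any(vs[on] != 2))
    return(list(ok = FALSE, msg = "a ring vertex has valence != 2 in the ring"))
  # walk the cycle
  adj <- split(c(re[, 2], re[, 1]), c(re[, 1], re[, 2]))
  start <- on[1]; prev <- -1L; cur <- start; count <- 0L
  repeat {
    nxt <- adj[[as.character(cur)]]
    nxt <- if (nxt[1] == prev) nxt[2] else nxt[1]
    prev <- cur; cur <- nxt; count <- count + 1L
    if (cur == start) break
    if (count > length(on)) return(list(ok = FALSE, msg = "ring walk did not close"))
  }
  if (count != length(on))
    return(list(ok = FALSE, msg = "ring has more than one component"))
  list(ok = TRUE, msg = "", n_edges = nrow(re))
}

#' Validate a surface mesh
#'
#' Diagnostic report on manifoldness, Euler characteristic, orientation
#' consistency, septin-ring integrity (if a ring is present) and minimum
#' face quality.
#'
#' @param mesh a `surface_mesh`.
#' @return a list with per-check results and an overall `pass` flag.
#' @export
validate_mesh <- function(mesh) {
  out <- list()
  V <- nrow(mesh$V); E <- nrow(mesh$edges); F <- nrow(mesh$F)
  out$euler <- V - E + F
  out$euler_ok <- out$euler == 2L
  et <- tryCatch(build_edge_table(mesh$F), error = function(e) conditionMessage(e))
  out$manifold_ok <- !is.character(et) && et$n_boundary == 0L
  if (is.character(et)) out$manifold_msg <- et
  else if (et$n_boundary > 0L)
    out$manifold_msg <- sprintf("boundary edge detected (%d open edges)", et$n_boundary)
  g <- tryCatch(compute_geometry(mesh), error = function(e) NULL)
  out$geometry_ok <- !is.null(g)
  if (!is.null(g)) {
    ctr <- colMeans(mesh$V)
    C <- (mesh$V[mesh$F[, 1], ] + mesh$V[mesh$F[, 2], ] + mesh$V[mesh$F[, 3], ]) / 3
    outward <- rowSums((C - matrix(ctr, F, 3, byrow = TRUE)) * g$face_normal)
    out$orientation_ok <- all(outward > 0)
    # closed-surface identity: area-weighted normals sum to ~0
    out$normal_closure <- sqrt(sum(colSums(g$face_normal * g$face_area)^2)) / g$total_area
    q <- 4 * sqrt(3) * g$face_area / tapply_face_l2(mesh, g)
    out$min_face_quality <- min(q)
  } else {
    out$orientation_ok <- FALSE
  }
  if (any(mesh$septin)) {
    chk <- check_septin_ring(mesh)
    out$ring_ok <- chk$ok
    two <- bud_component_count(mesh)
    out$two_regions_ok <- two == 2L
  } else {
    out$ring_ok <- TRUE
    out$two_regions_ok <- TRUE
  }
  out$pass <- out$euler_ok && out$manifold_ok && out$geometry_ok &&
    out$orientation_ok && out$ring_ok && out$two_regions_ok
  out
}

# sum of squared edge lengths per face (for the standard triangle quality
# measure q = 4*sqrt(3)*A / sum(l^2), 1 for equilateral)
tapply_face_l2 <- function(mesh, g) {
  V <- mesh$V; F <- mesh$F
  l1 <- rowSums((V[F[, 2], ] - V[F[, 1], ])^2)
  l2 <- rowSums((V[F[, 3], ] - V[F[, 2], ])^2)
  l3 <- rowSums((V[F[, 1], ] - V[F[, 3], ])^2)
  l1 + l2 + l3
}

# number of face components when dual connections across septin edges are cut
bud_component_count <- function(mesh) {
  m <- nrow(mesh$F)
  keep <- !mesh$septin & mesh$edge_faces[, 2] > 0L
  ef <- mesh$edge_faces[keep, , drop = FALSE]
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(ef))) {
    ra <- find(ef[k, 1]); rb <- find(ef[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}
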