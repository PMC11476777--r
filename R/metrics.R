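#' Bud surface area
#'
#' Sum of face areas over the bud region.
#'
#' @param mesh a `surface_mesh`.
#' @param geom optional geometry cache.
#' @return area (0 if the mesh has no bud faces).
#' @export
bud_area <- function(mesh, geom = compute_geometry(mesh)) {
  sum(geom$face_area[mesh$region == REGION_BUD])
}

#' Bud aspect ratio
#'
#' Ratio of the bud's long axis to its short axis. The default estimator
#' takes the principal axes of the centered bud vertex cloud and reports
#' the ratio of the largest to the smallest axis extent (max minus min of
#' the projections), which is rotation and scale invariant. The
#' alternative `"heightwidth"` estimator reports bud height above the neck
#' plane (mean z of the septin-ring vertices) over the maximal diameter
#' perpendicular to the bud axis.
#'
#' @param mesh a `surface_mesh` with a labeled bud.
#' @param method `"pca"` (default) or `"heightwidth"`.
#' @return scalar aspect ratio (>= 1 for `"pca"`).
#' @export
aspect_ratio <- function(mesh, method = c("pca", "heightwidth")) {
  method <- match.arg(method)
  bud_f <- mesh$region == REGION_BUD
  vid <- unique(as.vector(mesh$F[bud_f, ]))
  if (length(vid) < 4) stop("need at least 4 bud vertices")
  P <- mesh$V[vid, , drop = FALSE]
  if (method == "pca") {
    Pc <- sweep(P, 2, colMeans(P))
    sv <- svd(Pc, nu = 0)
    if (sv$d[3] < 1e-12 * sv$d[1]) stop("degenerate (coplanar) bud vertex cloud")
    proj <- Pc %*% sv$v
    ext <- apply(proj, 2, function(x) diff(range(x)))
    max(ext) / min(ext)
  } else {
    ring_v <- unique(as.vector(mesh$edges[mesh$septin, ]))
    if (length(ring_v) == 0) stop("height/width estimator needs a septin ring")
    neck_z <- mean(mesh$V[ring_v, 3])
    height <- max(P[, 3]) - neck_z
    width <- max(stats::dist(P[, 1:2]))
    height / width
  }
}

#' Polarization height of the active-Cdc42 region
#'
#' `PH` is the z-distance from the bud tip to the lower edge of the region
#' where the concentration is at least `fraction` times the maximum bud
#' concentration; `PH_total` is the z-distance from the tip to the mean z
#' of the septin-ring vertices (the bud neck); `relative_PH = PH/PH_total`
#' clipped to [0, 1] estimates the portion of the bud height occupied by
#' the polarization region.
#'
#' @param mesh a `surface_mesh` with bud and septin ring.
#' @param a per-vertex concentration.
#' @param fraction threshold fraction of the bud maximum (default 0.8).
#' @return list with `PH`, `PH_total`, `relative_PH`, `conc_max`.
#' @export
polarization_height <- function(mesh, a, fraction = 0.8) {
  stopifnot(length(a) == nrow(mesh$V))
  bud_f <- mesh$region == REGION_BUD
  vid <- unique(as.vector(mesh$F[bud_f, ]))
  conc_max <- max(a[vid])
  sel <- vid[a[vid] >= fraction * conc_max]
  if (length(sel) == 0) stop("no bud vertex reaches the threshold fraction")
  z_tip <- max(mesh$V[vid, 3])
  PH <- z_tip - min(mesh$V[sel, 3])
  ring_v <- unique(as.vector(mesh$edges[mesh$septin, ]))
  PH_total <- z_tip - mean(mesh$V[ring_v, 3])
  rel <- min(1, max(0, PH / PH_total))
  list(PH = PH, PH_total = PH_total, relative_PH = rel, conc_max = conc_max)
}

#' Ordinary least-squares fit of linear growth
#'
#' Fits `area = slope * time + intercept` and reports the fit quality;
#' used to verify that periodic constant-rate insertion yields linear bud
#' surface-area growth.
#'
#' @param time numeric vector (>= 3 values, non-constant).
#' @param area numeric vector of the same length.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear_growth <- function(time, area) {
  stopifnot(length(time) >= 3, length(area) == length(time))
  if (stats::sd(time) == 0) stop("time values are constant")
  fit <- stats::lm(area ~ time)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
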