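## Structured polar meshing of the five-layer knee cross-section, with an
## extruded tetrahedral 3D mode. Coordinates are stored in meters; the limb
## axis is z, angles are measured from the anterior midline.

mesh_region_names <- c("bone", "muscle", "fat", "wet_skin", "dry_skin")

## Radial node positions [m]: interfaces are always mesh circles, each layer
## subdivided uniformly. The 60 um dry-skin ring keeps at least one dedicated
## division, so the thin layer is resolved at every resolution level.
radial_divisions <- function(stack, resolution) {
  base <- c(bone = 3L, muscle = 5L, fat = 4L, wet_skin = 3L, dry_skin = 1L)
  n <- base * as.integer(resolution)
  radii <- layer_radii(stack) * 1e-3
  r <- 0
  out <- numeric(0); region <- integer(0)
  lo <- 0
  for (k in seq_along(radii)) {
    pts <- seq(lo, radii[k], length.out = n[k] + 1L)[-1L]
    out <- c(out, pts)
    region <- c(region, rep.int(k, n[k]))
    lo <- radii[k]
  }
  list(r = out, region = region)
}

## Uniform grid over a periodic or bounded interval, conformed to a set of
## required coordinates (electrode edges): required points are inserted
## exactly and uniform points closer than a quarter step are dropped, so
## patch extents are mesh-exact at every resolution.
conformed_grid <- function(uniform, required, periodic = FALSE) {
  if (!length(required)) return(sort(uniform))
  h <- min(diff(sort(uniform)))
  keep <- vapply(uniform, function(u) {
    d <- abs(u - required)
    if (periodic) d <- pmin(d, 2 * pi - d)
    all(d > 0.25 * h)
  }, logical(1))
  if (!periodic) keep[c(1L, length(keep))] <- TRUE  # never drop the ends
  sort(unique(c(uniform[keep], required)))
}

## Patch edges are weak singularities of the potential (equipotential patch
## meeting insulated skin), so the grid is graded geometrically towards each
## edge on both sides in addition to conforming to the edges exactly.
electrode_required_angles <- function(electrodes, r_out) {
  if (is.null(electrodes)) return(numeric(0))
  halfw <- electrodes$width_mm * 1e-3 / (2 * r_out)
  base <- as.vector(outer(c(-halfw, 0, halfw), electrodes$theta, `+`))
  edges <- as.vector(outer(c(-halfw, halfw), electrodes$theta, `+`))
  off <- halfw * c(-1 / 2, -1 / 4, -1 / 8, 1 / 8, 1 / 4, 1 / 2)
  a <- c(base, as.vector(outer(off, edges, `+`))) %% (2 * pi)
  sort(unique(round(a, 12)))
}

electrode_required_z <- function(electrodes) {
  if (is.null(electrodes)) return(numeric(0))
  zh <- electrodes$height_mm * 1e-3 / 2
  edges <- as.vector(outer(c(-zh, zh), electrodes$z_mm * 1e-3, `+`))
  z <- c(edges, as.vector(outer(zh * c(-1 / 4, 1 / 4), edges, `+`)))
  sort(unique(round(z, 12)))
}

triangulate_disc <- function(r, ring_region, theta) {
  nr <- length(r)
  ntheta <- length(theta)
  ## node 1 is the axis; ring i node j is 1 + (i-1)*ntheta + j
  x <- c(0, as.vector(outer(cos(theta), r)))
  y <- c(0, as.vector(outer(sin(theta), r)))
  idx <- function(i, j) 1L + (i - 1L) * ntheta + ((j - 1L) %% ntheta) + 1L
  j <- seq_len(ntheta)
  ## fan around the axis
  tri <- cbind(rep.int(1L, ntheta), idx(1L, j), idx(1L, j + 1L))
  region <- rep.int(ring_region[1L], ntheta)
  for (i in seq_len(nr - 1L)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
    tri <- rbind(tri, cbind(a, b, c2), cbind(a, c2, d))
    region <- c(region, rep.int(ring_region[i + 1L], 2L * ntheta))
  }
  node_angle <- c(NA_real_, rep(theta, nr))
  node_ring <- c(0L, rep(seq_len(nr), each = ntheta))
  list(p = cbind(x, y), tri = tri, region = region,
       node_angle = node_angle, node_ring = node_ring, nr = nr,
       ntheta = ntheta)
}

## Conforming split of a triangular prism into three tetrahedra using the
## smallest-global-index rule, so quad-face diagonals agree between neighbours.
prism_rotations <- matrix(c(
  0, 1, 2, 3, 4, 5,
  1, 2, 0, 4, 5, 3,
  2, 0, 1, 5, 3, 4,
  3, 5, 4, 0, 2, 1,
  4, 3, 5, 1, 0, 2,
  5, 4, 3, 2, 1, 0), nrow = 6, byrow = TRUE) + 1L

split_prisms <- function(prisms) {
  n <- nrow(prisms)
  amin <- max.col(-prisms, ties.method = "first")
  v <- matrix(0L, n, 6)
  for (case in 1:6) {
    sel <- amin == case
    if (any(sel)) v[sel, ] <- prisms[sel, prism_rotations[case, ], drop = FALSE]
  }
  flip <- pmin(v[, 2], v[, 6]) < pmin(v[, 3], v[, 5])
  tets <- matrix(0L, 3L * n, 4)
  i1 <- seq_len(n)
  tets[i1, ] <- cbind(v[, 1], v[, 2], v[, 3], ifelse(flip, v[, 6], v[, 5]))
  tets[n + i1, ] <- cbind(v[, 1],
                          ifelse(flip, v[, 2], v[, 5]),
                          ifelse(flip, v[, 6], v[, 3]),
                          ifelse(flip, v[, 5], v[, 6]))
  tets[2L * n + i1, ] <- cbind(v[, 1], v[, 5], v[, 6], v[, 4])
  tets
}

## P1 triangle geometry: area, basis gradients, in-plane stiffness blocks.
tri_geometry <- function(p, tri) {
  x1 <- p[tri[, 1], 1]; y1 <- p[tri[, 1], 2]
  x2 <- p[tri[, 2], 1]; y2 <- p[tri[, 2], 2]
  x3 <- p[tri[, 3], 1]; y3 <- p[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- abs(det) / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  ## 3x3 local stiffness flattened column-major into 9 columns
  Gt <- matrix(0, nrow(tri), 9)
  for (a in 1:3) for (b in 1:3)
    Gt[, (b - 1L) * 3L + a] <- area * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
  list(measure = area, gx = gx, gy = gy, gz = NULL, Gt = Gt, Gz = NULL,
       nloc = 3L)
}

## P1 tetrahedron geometry: volume, basis gradients, transverse (x,y) and
## axial (z) stiffness blocks, so an axially-fibered anisotropic muscle needs
## only two complex coefficients per element.
tet_geometry <- function(p, tet) {
  a <- p[tet[, 1], , drop = FALSE]
  e1 <- p[tet[, 2], , drop = FALSE] - a
  e2 <- p[tet[, 3], , drop = FALSE] - a
  e3 <- p[tet[, 4], , drop = FALSE] - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  vol <- abs(det) / 6
  ## rows of inv([e1;e2;e3]) give grad(lambda_2..4); grad(lambda_1) = -sum
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross(e2, e3) / det
  g3 <- cross(e3, e1) / det
  g4 <- cross(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  gx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
  gy <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
  gz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  Gt <- matrix(0, nrow(tet), 16)
  Gz <- matrix(0, nrow(tet), 16)
  for (aa in 1:4) for (bb in 1:4) {
    col <- (bb - 1L) * 4L + aa
    Gt[, col] <- vol * (gx[, aa] * gx[, bb] + gy[, aa] * gy[, bb])
    Gz[, col] <- vol * (gz[, aa] * gz[, bb])
  }
  list(measure = vol, gx = gx, gy = gy, gz = gz, Gt = Gt, Gz = Gz, nloc = 4L)
}

#' Discretized five-layer knee domain
#'
#' Builds a concentric-cylinder finite-element mesh of the personalized knee:
#' either a 2D cross-section (triangles, per-unit-length physics; fast) or a
#' 3D extrusion along the limb axis (tetrahedra). Layer interfaces are always
#' mesh surfaces and every element carries exactly one tissue label. Electrode
#' patches are resolved as node sets on the outer (skin) surface.
#'
#' @param stack A [layer_stack()].
#' @param mode `"2d"` or `"3d"`.
#' @param resolution Integer refinement level (>= 1); angular, radial and
#'   axial node counts all scale linearly with it.
#' @param electrodes An [electrode_config()], or NULL for a bare domain.
#' @param axial_length_mm Modelled segment length (3D mode).
#' @return An object of class `"knee_mesh"`.
#' @export
knee_mesh <- function(stack, mode = c("2d", "3d"), resolution = 1,
                      electrodes = default_electrodes(match.arg(mode)),
                      axial_length_mm = 100) {
  mode <- match.arg(mode)
  if (!inherits(stack, "layer_stack"))
    stop_validation("'stack' must be a layer_stack")
  resolution <- as.integer(resolution)
  if (resolution < 1L) stop_validation("'resolution' must be >= 1")
  rd <- radial_divisions(stack, resolution)
  r_out <- max(rd$r)
  ntheta0 <- 48L * resolution
  theta <- conformed_grid(seq(0, 2 * pi, length.out = ntheta0 + 1L)[-(ntheta0 + 1L)],
                          electrode_required_angles(electrodes, r_out),
                          periodic = TRUE)
  disc <- triangulate_disc(rd$r, rd$region, theta)
  ntheta <- length(theta)

  if (mode == "2d") {
    geom <- tri_geometry(disc$p, disc$tri)
    m <- structure(list(
      mode = "2d", p = disc$p, elems = disc$tri, region = disc$region,
      region_names = mesh_region_names, geom = geom,
      centroid = (disc$p[disc$tri[, 1], , drop = FALSE] +
                  disc$p[disc$tri[, 2], , drop = FALSE] +
                  disc$p[disc$tri[, 3], , drop = FALSE]) / 3,
      node_angle = disc$node_angle,
      outer_nodes = which(disc$node_ring == disc$nr),
      node_z = NULL, r_out = r_out, ntheta = ntheta,
      resolution = resolution, stack = stack), class = "knee_mesh")
  } else {
    nz0 <- 10L * resolution
    L <- axial_length_mm * 1e-3
    zreq <- electrode_required_z(electrodes)
    zreq <- zreq[zreq > -L / 2 & zreq < L / 2]
    zs <- conformed_grid(seq(-L / 2, L / 2, length.out = nz0 + 1L), zreq)
    nz <- length(zs) - 1L
    npl <- nrow(disc$p)
    p3 <- cbind(disc$p[rep(seq_len(npl), nz + 1L), , drop = FALSE],
                rep(zs, each = npl))
    ntri <- nrow(disc$tri)
    prisms <- matrix(0L, ntri * nz, 6)
    for (l in seq_len(nz)) {
      off_b <- (l - 1L) * npl; off_t <- l * npl
      prisms[(l - 1L) * ntri + seq_len(ntri), ] <-
        cbind(disc$tri + off_b, disc$tri + off_t)
    }
    tets <- split_prisms(prisms)
    region <- rep.int(rep(disc$region, nz), 3L)
    geom <- tet_geometry(p3, tets)
    m <- structure(list(
      mode = "3d", p = p3, elems = tets, region = region,
      region_names = mesh_region_names, geom = geom,
      centroid = (p3[tets[, 1], , drop = FALSE] + p3[tets[, 2], , drop = FALSE] +
                  p3[tets[, 3], , drop = FALSE] + p3[tets[, 4], , drop = FALSE]) / 4,
      node_angle = rep(disc$node_angle, nz + 1L),
      outer_nodes = which(rep(disc$node_ring, nz + 1L) == disc$nr),
      node_z = p3[, 3], r_out = r_out, ntheta = ntheta, nz = nz,
      axial_length_mm = axial_length_mm,
      cap_nodes = list(bottom = seq_len(npl),
                       top = nz * npl + seq_len(npl)),
      resolution = resolution, stack = stack), class = "knee_mesh")
  }
  if (!is.null(electrodes)) {
    m$electrodes <- electrodes
    m$patches <- electrode_nodes(m, electrodes)
  }
  m
}

#' @export
print.knee_mesh <- function(x, ...) {
  cat(sprintf("knee_mesh (%s): %d nodes, %d elements, resolution %d\n",
              x$mode, nrow(x$p), nrow(x$elems), x$resolution))
  invisible(x)
}

#' Per-region measures of a knee mesh
#'
#' Sum of element areas (2D, m^2) or volumes (3D, m^3) by tissue region, for
#' comparison with the analytic concentric-shell formulas.
#'
#' @param mesh A [knee_mesh()].
#' @return Named numeric vector over the five regions.
#' @export
region_measures <- function(mesh) {
  v <- vapply(seq_along(mesh$region_names), function(k)
    sum(mesh$geom$measure[mesh$region == k]), numeric(1))
  names(v) <- mesh$region_names
  v
}

angular_distance <- function(a, b) {
  d <- a - b
  atan2(sin(d), cos(d))
}

#' Electrode patch node sets
#'
#' Resolves each electrode patch of a configuration to the outer-surface mesh
#' nodes it covers. Patches must contain at least two nodes (refine the mesh
#' or widen the patch otherwise) and must not partially overlap; a sense patch
#' exactly coinciding with a drive patch is allowed as the degenerate bipolar
#' placement.
#'
#' @param mesh A [knee_mesh()].
#' @param electrodes An [electrode_config()].
#' @return List of four integer vectors of node indices.
#' @export
electrode_nodes <- function(mesh, electrodes) {
  if (!inherits(electrodes, "electrode_config"))
    stop_validation("'electrodes' must be an electrode_config")
  halfw <- electrodes$width_mm * 1e-3 / (2 * mesh$r_out)
  tol <- 1e-9
  out <- vector("list", 4L)
  for (k in 1:4) {
    ang_ok <- abs(angular_distance(mesh$node_angle[mesh$outer_nodes],
                                   electrodes$theta[k])) <= halfw + tol
    if (mesh$mode == "3d") {
      zc <- electrodes$z_mm[k] * 1e-3
      zh <- electrodes$height_mm * 1e-3 / 2
      L <- mesh$axial_length_mm * 1e-3
      if (zc - zh < -L / 2 - tol || zc + zh > L / 2 + tol)
        stop_validation(sprintf("electrode patch %d exceeds the modelled surface (z = %g mm)",
                                k, electrodes$z_mm[k]))
      z_ok <- abs(mesh$node_z[mesh$outer_nodes] - zc) <= zh + tol
      sel <- ang_ok & z_ok
    } else sel <- ang_ok
    out[[k]] <- mesh$outer_nodes[sel]
    if (length(out[[k]]) < 2L)
      stop_validation(sprintf(
        "electrode patch %d resolves to %d mesh node(s); refine the mesh or widen the patch",
        k, length(out[[k]])))
  }
  ## partial overlap is a configuration error; exact coincidence of a sense
  ## patch with a drive patch is the degenerate bipolar case
  pairs <- utils::combn(4, 2)
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    common <- intersect(out[[a]], out[[b]])
    if (length(common) &&
        !(setequal(out[[a]], out[[b]]) && xor(a <= 2, b <= 2)))
      stop_validation(sprintf("electrode patches %d and %d overlap", a, b))
  }
  names(out) <- electrodes$roles
  out
}
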