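# Synthetic template geometries: icosphere, ellipsoid, bent tube.

#' Icosphere template mesh
#'
#' Subdivided icosahedron projected to a sphere of the given radius. At
#' subdivision level s the mesh has 10*4^s + 2 vertices.
#'
#' @param radius Sphere radius (mm).
#' @param subdivisions Subdivision level (default 3: 642 vertices).
#' @return A `surface_mesh`.
#' @export
icosphere <- function(radius = 10, subdivisions = 3L) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    res <- subdivide_once(v, f)
    v <- res$v; f <- res$f
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

# 1-to-4 loop-style split with midpoint deduplication
subdivide_once <- function(v, f) {
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  ukey <- unique(ekey)
  mid_idx <- nrow(v) + match(ekey, ukey)
  upair <- do.call(rbind, strsplit(ukey, " ", fixed = TRUE))
  a <- as.integer(upair[, 1]); b <- as.integer(upair[, 2])
  mids <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  m12 <- mid_idx[seq_len(nrow(f))]
  m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
  m31 <- mid_idx[2L * nrow(f) + seq_len(nrow(f))]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(m12, f[, 2], m23),
                cbind(m31, m23, f[, 3]),
                cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = newf)
}

#' Ellipsoid template mesh
#'
#' Icosphere mapped onto an ellipsoid with the given semi-axes; a simple
#' stand-in for an amygdala- or hippocampus-scale blob.
#'
#' @param semi_axes Length-3 semi-axes (mm), e.g. `c(17, 8, 7)`.
#' @param subdivisions Icosphere subdivision level.
#' @return A `surface_mesh`.
#' @export
ellipsoid_mesh <- function(semi_axes = c(17, 8, 7), subdivisions = 4L) {
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be three positive lengths", call. = FALSE)
  sph <- icosphere(1, subdivisions)
  v <- sweep(sph$vertices, 2L, semi_axes, "*")
  surface_mesh(v, sph$faces)
}

#' Thomsen approximation to ellipsoid surface area
#' @param semi_axes Length-3 semi-axes (mm).
#' @return Approximate area (mm^2), relative error < 1.1%.
#' @export
ellipsoid_area_thomsen <- function(semi_axes) {
  p <- 1.6075
  a <- semi_axes[1]^p; b <- semi_axes[2]^p; c <- semi_axes[3]^p
  4 * pi * ((a * b + a * c + b * c) / 3)^(1 / p)
}

#' Bent-tube ("hippocampus-like") template mesh
#'
#' Capped tube swept along a circular arc: a curved elongated blob with
#' hippocampal proportions. Closed and manifold (quad strips split into
#' triangles, triangle-fan end caps).
#'
#' @param arc_radius Radius of the centreline arc (mm).
#' @param tube_radius Tube radius (mm).
#' @param arc_angle Arc span (radians), default 2.2.
#' @param n_u Rings along the arc (default 24).
#' @param n_v Vertices around the tube (default 16).
#' @return A `surface_mesh`.
#' @export
bent_tube_mesh <- function(arc_radius = 16, tube_radius = 5,
                           arc_angle = 2.2, n_u = 24L, n_v = 16L) {
  if (arc_radius <= tube_radius)
    stop("`arc_radius` must exceed `tube_radius`", call. = FALSE)
  th <- seq(-arc_angle / 2, arc_angle / 2, length.out = n_u)
  centre <- cbind(arc_radius * cos(th), arc_radius * sin(th), 0)
  tangent <- cbind(-sin(th), cos(th), 0)
  normal <- cbind(cos(th), sin(th), 0)      # radial (in-plane)
  binorm <- matrix(rep(c(0, 0, 1), each = n_u), ncol = 3)
  ph <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  verts <- matrix(0, n_u * n_v, 3)
  for (i in seq_len(n_u)) {
    ring <- centre[rep(i, n_v), ] +
      tube_radius * (outer(cos(ph), normal[i, ]) + outer(sin(ph), binorm[i, ]))
    verts[(i - 1L) * n_v + seq_len(n_v), ] <- ring
  }
  idx <- function(i, j) (i - 1L) * n_v + ((j - 1L) %% n_v) + 1L
  faces <- list()
  for (i in seq_len(n_u - 1L)) for (j in seq_len(n_v)) {
    a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    faces[[length(faces) + 1L]] <- rbind(c(a, b, cc), c(a, cc, d))
  }
  # end caps: apex at arc ends, fanned to the first/last ring
  apex1 <- nrow(verts) + 1L; apex2 <- nrow(verts) + 2L
  cap1 <- centre[1L, ] - tangent[1L, ] * tube_radius
  cap2 <- centre[n_u, ] + tangent[n_u, ] * tube_radius
  verts <- rbind(verts, cap1, cap2)
  for (j in seq_len(n_v)) {
    faces[[length(faces) + 1L]] <- rbind(
      c(apex1, idx(1L, j), idx(1L, j + 1L)),
      c(apex2, idx(n_u, j + 1L), idx(n_u, j)))
  }
  mesh <- surface_mesh(verts, do.call(rbind, faces), validate = FALSE)
  orient_outward(mesh)
}

#' Digitize a solid ball into a binary mask
#'
#' Voxelizes a sphere of the given radius (voxel units) on an isotropic
#' grid with a padding margin, for testing iso-surface extraction.
#'
#' @param radius Ball radius in voxels.
#' @param spacing Isotropic voxel spacing (mm), default 1.
#' @param pad Background margin in voxels, default 3.
#' @return A `binary_mask`.
#' @export
digitized_ball <- function(radius = 10, spacing = 1, pad = 3L) {
  n <- 2L * (ceiling(radius) + pad) + 1L
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  affine <- diag(c(spacing, spacing, spacing, 1))
  binary_mask(array(d2 <= radius^2, dim = c(n, n, n)), affine)
}
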