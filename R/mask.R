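#' Construct a binary mask
#'
#' A voxel grid of {0,1} with a voxel-to-world affine. Voxel indices are
#' 0-based in the affine convention (NIfTI): world = A %*% c(i, j, k, 1)
#' for the voxel at `data[i+1, j+1, k+1]`.
#'
#' @param data 3D array; nonzero entries are foreground.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, affine = diag(4)) {
  data <- (as.array(data) != 0) * 1
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  if (sum(data) == 0) stop("empty mask: no foreground voxels", call. = FALSE)
  structure(list(data = data, affine = affine), class = "binary_mask")
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Uses the NIfTI xform (sform preferred) as the voxel-to-world affine.
#' Voxels with intensity > `threshold` are foreground.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param threshold Foreground threshold, default 0.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, threshold = 0) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  binary_mask(as.array(img) > threshold, affine)
}

#' Voxel spacing of a mask (mm)
#' @param mask A `binary_mask`.
#' @return Length-3 numeric vector.
#' @export
voxel_spacing <- function(mask) {
  A <- mask$affine[1:3, 1:3]
  sqrt(colSums(A^2))
}

# Kuhn 6-tetrahedra decomposition of the unit cube, all sharing the main
# diagonal c0 -- c6. Corner order: bit pattern (x, y, z).
.cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
.cube_tets <- rbind(
  c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
  c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))

#' Extract an iso-surface mesh from a binary mask
#'
#' Marching tetrahedra on the voxel lattice (node-centered values, Kuhn
#' 6-tet cube decomposition): a watertight, edge-manifold triangle surface
#' at `level`, mapped to world mm through the mask affine. The largest
#' connected component is returned. Optional Taubin smoothing (off by
#' default) relaxes the staircase without shrinking the surface.
#'
#' @param mask A `binary_mask` (or plain 3D array).
#' @param level Iso-level in (0,1); default 0.5.
#' @param smooth_iter Taubin smoothing iterations (0 = none).
#' @return A `surface_mesh` in world coordinates.
#' @export
mesh_from_mask <- function(mask, level = 0.5, smooth_iter = 0L) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  vol <- mask$data
  d <- dim(vol)
  if (touches_boundary(vol))
    stop("foreground touches the grid boundary; pad the mask with a layer ",
         "of background voxels before meshing", call. = FALSE)
  inside <- vol > level

  # candidate cells: 2x2x2 node blocks containing both signs
  sub <- which(inside, arr.ind = TRUE)
  lo <- pmax(apply(sub, 2L, min) - 1L, 1L)
  hi <- pmin(apply(sub, 2L, max) + 1L, d - 1L)
  cells <- as.matrix(expand.grid(i = lo[1L]:hi[1L], j = lo[2L]:hi[2L],
                                 k = lo[3L]:hi[3L]))

  lin <- function(ijk) ijk[, 1L] + d[1L] * (ijk[, 2L] - 1L) +
    d[1L] * d[2L] * (ijk[, 3L] - 1L)
  corner_lin <- sapply(seq_len(8L), function(c8) {
    lin(sweep(cells, 2L, .cube_corners[c8, ], "+"))
  })
  if (is.null(dim(corner_lin))) corner_lin <- matrix(corner_lin, nrow = 1L)
  ins8 <- matrix(inside[corner_lin], nrow = nrow(cells))
  mixed <- rowSums(ins8) %in% 1:7
  corner_lin <- corner_lin[mixed, , drop = FALSE]
  ins8 <- ins8[mixed, , drop = FALSE]

  # accumulate triangles as triples of lattice-edge keys
  tri_a <- character(0); tri_b <- character(0); tri_c <- character(0)
  flip <- logical(0)
  vals <- vol
  edge_key <- function(p, q) paste(pmin(p, q), pmax(p, q))
  for (ci in seq_len(nrow(corner_lin))) {
    cl <- corner_lin[ci, ]
    cin <- ins8[ci, ]
    for (t6 in seq_len(6L)) {
      tv <- .cube_tets[t6, ]
      tin <- cin[tv]
      ni <- sum(tin)
      if (ni == 0L || ni == 4L) next
      ip <- cl[tv[tin]]; op <- cl[tv[!tin]]
      if (ni == 1L || ni == 3L) {
        apex <- if (ni == 1L) ip else op
        base <- if (ni == 1L) op else ip
        e <- c(edge_key(apex, base[1L]), edge_key(apex, base[2L]),
               edge_key(apex, base[3L]))
        tri_a <- c(tri_a, e[1L]); tri_b <- c(tri_b, e[2L]); tri_c <- c(tri_c, e[3L])
        flip <- c(flip, FALSE)
      } else {  # 2 in / 2 out: quad split into two triangles
        e11 <- edge_key(ip[1L], op[1L]); e12 <- edge_key(ip[1L], op[2L])
        e21 <- edge_key(ip[2L], op[1L]); e22 <- edge_key(ip[2L], op[2L])
        tri_a <- c(tri_a, e11, e11); tri_b <- c(tri_b, e12, e22)
        tri_c <- c(tri_c, e22, e21)
        flip <- c(flip, FALSE, FALSE)
      }
    }
  }
  if (length(tri_a) == 0L) stop("no iso-surface found at level ", level, call. = FALSE)

  keys <- unique(c(tri_a, tri_b, tri_c))
  faces <- cbind(match(tri_a, keys), match(tri_b, keys), match(tri_c, keys))

  # vertex positions: interpolate the crossing along each lattice edge
  kp <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  p1 <- as.integer(kp[, 1L]); p2 <- as.integer(kp[, 2L])
  v1 <- vals[p1]; v2 <- vals[p2]
  tt <- (level - v1) / (v2 - v1)
  ijk1 <- lin_to_ijk(p1, d); ijk2 <- lin_to_ijk(p2, d)
  vox <- ijk1 + tt * (ijk2 - ijk1)          # 1-based voxel coords
  world <- voxel_to_world(vox - 1, mask$affine)

  mesh <- surface_mesh(world, faces, validate = FALSE)
  mesh <- orient_outward(fix_winding(mesh, vox, p1, p2, tt, vals, d, level))
  mesh <- largest_component(mesh)
  if (smooth_iter > 0L) mesh <- taubin_smooth(mesh, smooth_iter)
  validate_mesh(mesh)
  mesh
}

lin_to_ijk <- function(p, d) {
  p0 <- p - 1L
  i <- p0 %% d[1L]
  j <- (p0 %/% d[1L]) %% d[2L]
  k <- p0 %/% (d[1L] * d[2L])
  cbind(i, j, k) + 1
}

voxel_to_world <- function(vox0, affine) {
  xyz1 <- cbind(vox0, 1)
  out <- xyz1 %*% t(affine)
  out[, 1:3, drop = FALSE]
}

touches_boundary <- function(vol) {
  d <- dim(vol)
  any(vol[c(1L, d[1L]), , ] != 0) || any(vol[, c(1L, d[2L]), ] != 0) ||
    any(vol[, , c(1L, d[3L])] != 0)
}

# orient each face so its (voxel-space) normal points away from the inside
# nodes of its generating lattice edges; the affine's handedness is fixed
# globally afterwards by orient_outward().
fix_winding <- function(mesh, vox, p1, p2, tt, vals, d, level) {
  # inward direction at a vertex: from the outside node toward the inside node
  inside1 <- vals[p1] > level
  ijk1 <- lin_to_ijk(p1, d); ijk2 <- lin_to_ijk(p2, d)
  dir_in <- (ijk1 - ijk2)
  dir_in[!inside1, ] <- -dir_in[!inside1, , drop = FALSE]
  f <- mesh$faces
  e1 <- vox[f[, 2L], , drop = FALSE] - vox[f[, 1L], , drop = FALSE]
  e2 <- vox[f[, 3L], , drop = FALSE] - vox[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  # average inward direction over the face corners (voxel axes)
  din <- (dir_in[f[, 1L], , drop = FALSE] + dir_in[f[, 2L], , drop = FALSE] +
            dir_in[f[, 3L], , drop = FALSE])
  s <- rowSums(cr * din)
  swap <- s > 0  # normal should point outward (opposite the inward dir)
  if (any(swap)) {
    tmp <- f[swap, 2L]
    f[swap, 2L] <- f[swap, 3L]
    f[swap, 3L] <- tmp
    mesh$faces <- f
  }
  mesh
}

orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Keep the largest connected component (by area)
#' @param mesh A `surface_mesh`.
#' @return A `surface_mesh`, reindexed.
#' @export
largest_component <- function(mesh) {
  comp <- vertex_components(mesh)
  if (length(unique(comp)) == 1L) return(mesh)
  fa <- face_areas(mesh)
  fcomp <- comp[mesh$faces[, 1L]]
  keep <- as.integer(names(which.max(tapply(fa, fcomp, sum))))
  vkeep <- which(comp == keep)
  remap <- integer(n_vertices(mesh))
  remap[vkeep] <- seq_along(vkeep)
  fkeep <- mesh$faces[fcomp == keep, , drop = FALSE]
  surface_mesh(mesh$vertices[vkeep, , drop = FALSE],
               matrix(remap[fkeep], ncol = 3L), validate = FALSE)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Two-step low-pass filter (shrink then inflate) with uniform edge
#' weights; volume-preserving to first order.
#'
#' @param mesh A `surface_mesh`.
#' @param iterations Number of lambda/mu passes.
#' @param lambda,mu Step sizes; defaults 0.5 and -0.53.
#' @return Smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 5L, lambda = 0.5, mu = -0.53) {
  ed <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  W <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                            j = c(ed[, 2L], ed[, 1L]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(W)
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    for (step in c(lambda, mu)) {
      lap <- as.matrix(W %*% v) / deg - v
      v <- v + step * lap
    }
  }
  surface_mesh(v, mesh$faces, validate = FALSE)
}
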