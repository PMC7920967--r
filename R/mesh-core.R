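#' Construct a triangle mesh
#'
#' A `surface_mesh` is the geometric substrate of the whole pipeline: an
#' n x 3 matrix of vertex coordinates in world millimetres and an m x 3
#' integer matrix of vertex indices (1-based internally; file formats use
#' 0-based indices on disk).
#'
#' @param vertices Numeric matrix (n x 3), vertex coordinates in mm.
#' @param faces Integer matrix (m x 3), triangle corner indices (1-based).
#' @param validate Run invariant checks (index range, positive face areas,
#'   edge-manifoldness, consistent winding). Default `TRUE`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns (triangles only)", call. = FALSE)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Validate triangle-mesh invariants
#'
#' Checks index range, finite coordinates, strictly positive face areas,
#' edge-manifoldness (each undirected edge in at most two faces) and
#' consistent face winding (no directed edge repeated).
#'
#' @param mesh A `surface_mesh`.
#' @param require_connected Also require a single connected component.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, require_connected = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("mesh has non-finite vertex coordinates", call. = FALSE)
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, ", nrow(v), "]", call. = FALSE)
    fa <- face_areas(mesh)
    if (any(fa <= 0)) {
      bad <- which(fa <= 0)[1L]
      stop("degenerate face with non-positive area: face ", bad, call. = FALSE)
    }
    ed <- directed_edges(f)
    key <- paste(ed[, 1L], ed[, 2L])
    if (anyDuplicated(key))
      stop("inconsistent face winding: directed edge repeated", call. = FALSE)
    ukey <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    if (any(table(ukey) > 2L))
      stop("mesh is not edge-manifold: an edge is shared by >2 faces", call. = FALSE)
  }
  if (require_connected && n_components(mesh) != 1L)
    stop("mesh must be a single connected component", call. = FALSE)
  invisible(mesh)
}

# all directed edges (3 per face), rows (from,to)
directed_edges <- function(faces) {
  rbind(faces[, c(1L, 2L), drop = FALSE],
        faces[, c(2L, 3L), drop = FALSE],
        faces[, c(3L, 1L), drop = FALSE])
}

#' Undirected edge list of a mesh
#' @param mesh A `surface_mesh`.
#' @return Two-column integer matrix of unique undirected edges.
#' @export
mesh_edges <- function(mesh) {
  ed <- directed_edges(mesh$faces)
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  unique(ed)
}

n_components <- function(mesh) {
  comp <- vertex_components(mesh)
  length(unique(comp))
}

# connected-component label per vertex (BFS over the edge graph)
vertex_components <- function(mesh) {
  n <- n_vertices(mesh)
  ed <- mesh_edges(mesh)
  adj <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- nb
    }
  }
  comp
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face triangle areas
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#'
#' Sum of triangle areas, in mm^2. This is the quantity the patch-size rule
#' (target average patch area) operates on.
#'
#' @param mesh A `surface_mesh`.
#' @return Scalar area (mm^2).
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Barycentric per-vertex areas
#'
#' Each vertex receives one third of the area of every incident triangle,
#' so the vertex areas are always positive and sum exactly to the total
#' surface area. This is the area convention used by the lumped mass matrix
#' and by the surface-Jacobian expansion factor.
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric vector, length `nrow(mesh$vertices)`, in mm^2.
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  va <- numeric(n_vertices(mesh))
  third <- fa / 3
  for (j in 1:3) {
    acc <- rowsum(third, mesh$faces[, j])
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc[, 1L]
  }
  va
}

#' Outward vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit
#' length. Assumes consistent outward winding.
#'
#' @param mesh A `surface_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # area-weighted face normals (2A * n_hat)
  vn <- matrix(0, n_vertices(mesh), 3L)
  for (j in 1:3) {
    acc <- rowsum(cr, mesh$faces[, j])
    idx <- as.integer(rownames(acc))
    vn[idx, ] <- vn[idx, ] + acc
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem signed volume; positive for outward-wound closed
#' surfaces.
#'
#' @param mesh A `surface_mesh`.
#' @return Scalar volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
          a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
          a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  sum(det3) / 6
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh A `surface_mesh`.
#' @param rotation 3 x 3 matrix applied on the right of row vectors' transpose.
#' @param translation Length-3 offset.
#' @return Transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, translation, "+")
  surface_mesh(v, mesh$faces, validate = FALSE)
}
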