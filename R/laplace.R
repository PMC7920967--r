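#' Discrete Laplace-Beltrami operator of a triangle mesh
#'
#' Linear finite-element (cotangent) stiffness matrix with a barycentric
#' lumped mass vector. For the stiffness K, `K[i,j] = -(cot a_ij +
#' cot b_ij)/2` over the one or two triangles opposite edge (i,j), with
#' diagonal entries making every row sum to zero; K is symmetric positive
#' semidefinite and annihilates constants. The lumped mass assigns each
#' vertex one third of its incident triangle area, so the masses sum to
#' the total surface area.
#'
#' @param mesh A connected, manifold `surface_mesh`.
#' @return An object of class `laplace_operator` with elements `stiffness`
#'   (sparse symmetric n x n, class `dsCMatrix`) and `mass` (numeric n,
#'   mm^2).
#' @export
laplace_beltrami <- function(mesh) {
  validate_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # cotangent at the corner opposite each edge, per face
  for (corner in 1:3) {
    o <- f[, corner]                      # opposite vertex
    a <- f[, corner %% 3L + 1L]
    b <- f[, (corner + 1L) %% 3L + 1L]    # edge (a, b)
    u <- v[a, , drop = FALSE] - v[o, , drop = FALSE]
    w <- v[b, , drop = FALSE] - v[o, , drop = FALSE]
    cross2 <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
                    u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
                    u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
    sinA <- sqrt(rowSums(cross2^2))
    cosA <- rowSums(u * w)
    cot <- cosA / sinA
    if (any(!is.finite(cot))) {
      bad <- which(!is.finite(cot))[1L]
      stop("non-finite cotangent weight at face ", bad,
           " (degenerate triangle)", call. = FALSE)
    }
    half <- cot / 2
    ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b)
    xx <- c(xx, -half, -half, half, half)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(stiffness = K, mass = vertex_areas(mesh), n = n),
            class = "laplace_operator")
}

#' @export
print.laplace_operator <- function(x, ...) {
  cat(sprintf("<laplace_operator> n = %d, total mass %.2f mm^2\n",
              x$n, sum(x$mass)))
  invisible(x)
}

#' Low eigenpairs of the Laplace-Beltrami operator
#'
#' Solves the generalized symmetric eigenproblem K phi = lambda M phi with
#' the lumped mass M, via the equivalent dense symmetric problem
#' M^-1/2 K M^-1/2. Eigenvalues are returned in ascending order (the first
#' is 0 for a connected mesh, with a constant eigenvector); eigenvectors
#' are mass-orthonormal: t(Phi) %*% diag(M) %*% Phi = I.
#'
#' @param op A `laplace_operator` (or a `surface_mesh`, for convenience).
#' @param k Number of eigenpairs, 1 <= k < n.
#' @return List with `values` (length k, ascending, >= 0 up to round-off)
#'   and `vectors` (n x k).
#' @export
lb_eigendecomposition <- function(op, k) {
  if (inherits(op, "surface_mesh")) op <- laplace_beltrami(op)
  n <- op$n
  if (k < 1 || k >= n)
    stop("`k` must satisfy 1 <= k < ", n, call. = FALSE)
  s <- 1 / sqrt(op$mass)
  A <- as.matrix(op$stiffness) * tcrossprod(s)   # M^-1/2 K M^-1/2
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  ord <- n:(n - k + 1L)                           # eigen() sorts descending
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE] * s  # back-substitute M^-1/2
  values[values < 0 & values > -1e-9 * max(abs(values), 1)] <- 0
  list(values = values, vectors = vectors)
}
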