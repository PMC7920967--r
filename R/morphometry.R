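#' Rigid superposition of one mesh onto another
#'
#' Least-squares rotation + translation (Kabsch), no scaling: overall size
#' is biological signal here and is handled downstream by the ICV
#' covariate, not removed by the alignment. Requires shared vertex
#' topology (one-to-one vertex correspondence).
#'
#' @param mesh,reference `surface_mesh` objects with identical face lists.
#' @return The aligned `surface_mesh`, with attributes `rotation`,
#'   `translation` and `rmsd`.
#' @export
rigid_align <- function(mesh, reference) {
  check_shared_topology(mesh, reference)
  x <- mesh$vertices; y <- reference$vertices
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- crossprod(xc, yc)
  sv <- svd(s)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(xc %*% t(R), 2L, cy, "+")
  out <- surface_mesh(aligned, mesh$faces, validate = FALSE)
  attr(out, "rotation") <- R
  attr(out, "translation") <- as.numeric(cy - R %*% cx)
  attr(out, "rmsd") <- sqrt(mean(rowSums((aligned - y)^2)))
  out
}

check_shared_topology <- function(a, b) {
  if (!identical(dim(a$vertices), dim(b$vertices)) ||
      !identical(a$faces, b$faces))
    stop("meshes do not share vertex topology (vertex count and face list ",
         "must be identical); surfaces without correspondence cannot be ",
         "compared by this pipeline", call. = FALSE)
  invisible(TRUE)
}

#' Population surface template from corresponding meshes
#'
#' Iterative vertex-wise mean: every subject is rigidly aligned (no
#' scaling) to the running mean, the mean is recomputed, and the loop
#' stops when the mean vertex displacement of the template falls below
#' `tol` (default 1e-4 mm) or after `max_iter` iterations. All meshes must
#' share vertex topology. The result is the common coordinate system in
#' which expansion factors are measured.
#'
#' @param meshes List of `surface_mesh` objects with identical face lists.
#' @param tol Convergence tolerance on mean vertex displacement (mm).
#' @param max_iter Maximum iterations (default 20).
#' @return A `surface_mesh` template.
#' @export
build_template <- function(meshes, tol = 1e-4, max_iter = 20L) {
  if (length(meshes) < 1L) stop("need at least one mesh", call. = FALSE)
  for (m in meshes) check_shared_topology(m, meshes[[1L]])
  template <- meshes[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(meshes, rigid_align, reference = template)
    vmean <- Reduce(`+`, lapply(aligned, `[[`, "vertices")) / length(meshes)
    disp <- mean(sqrt(rowSums((vmean - template$vertices)^2)))
    template <- surface_mesh(vmean, meshes[[1L]]$faces, validate = FALSE)
    if (disp < tol) break
  }
  template
}

#' Per-vertex surface-Jacobian expansion factors
#'
#' The expansion factor at a vertex is the ratio of the subject's
#' barycentric vertex area to the template's: > 1 means local expansion,
#' < 1 local atrophy. The template-vertex-area-weighted mean of the field
#' equals the total-area ratio exactly. `log = TRUE` returns log-Jacobians
#' instead of raw factors (a documented deviation from the default raw
#' scale).
#'
#' @param template,subject Corresponding `surface_mesh` objects.
#' @param log Return natural-log expansion factors.
#' @return Numeric vector (length = vertex count), the expansion field.
#' @export
surface_jacobian <- function(template, subject, log = FALSE) {
  check_shared_topology(subject, template)
  at <- vertex_areas(template)
  if (any(at <= 0)) stop("template has a zero-area vertex", call. = FALSE)
  f <- vertex_areas(subject) / at
  if (log) base::log(f) else f
}

#' Assemble the patches x subjects feature matrix
#'
#' Entry (p, i) is the patch-p mean expansion factor of subject i; column
#' order follows `subject_ids`, which must match the covariate table order
#' used downstream.
#'
#' @param parc A `parcellation` of the template.
#' @param fields List of expansion fields (one per subject, template
#'   vertex order).
#' @param subject_ids Character vector of unique subject ids.
#' @param ... Passed to [patch_mean_features()].
#' @return Numeric matrix k x n_subjects with dimnames
#'   (`patch_<label>`, subject id).
#' @export
assemble_feature_matrix <- function(parc, fields, subject_ids, ...) {
  if (length(fields) != length(subject_ids))
    stop("one field per subject id required", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  cols <- lapply(fields, function(f) patch_mean_features(parc, f, ...))
  Y <- do.call(cbind, cols)
  dimnames(Y) <- list(paste0("patch_", seq_len(parc$k) - 1L),
                      as.character(subject_ids))
  Y
}

#' Write / read a feature matrix as TSV
#'
#' Rows are patches, columns subjects; first column `patch` holds the
#' 0-based patch label.
#'
#' @param Y Feature matrix from [assemble_feature_matrix()].
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_features <- function(Y, path) {
  df <- data.frame(patch = rownames(Y), Y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  Y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Y) <- df[[1L]]
  Y
}

#' Tidy a feature matrix to long form
#' @param Y Feature matrix (patches x subjects).
#' @return Tibble with columns patch (0-based integer), id, expansion.
#' @export
tidy_features <- function(Y) {
  tibble::tibble(
    patch = rep(seq_len(nrow(Y)) - 1L, times = ncol(Y)),
    id = rep(colnames(Y), each = nrow(Y)),
    expansion = as.numeric(Y))
}
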