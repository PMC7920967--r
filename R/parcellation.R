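#' Patch count from the average-area rule
#'
#' The template is cut into the number of patches whose average surface
#' area is closest to a target (default 150 mm^2):
#' `k = max(1, round(total_area / target_area))`, rounding half away from
#' zero. On a hippocampus-scale surface (~1350 mm^2) this gives 9 patches;
#' on an amygdala-scale surface (~600 mm^2) it gives 4.
#'
#' @param total_area Total surface area (mm^2), > 0.
#' @param target_area Target average patch area (mm^2), default 150.
#' @return Integer patch count k >= 1.
#' @export
choose_patch_count <- function(total_area, target_area = 150) {
  if (!is.finite(total_area) || total_area <= 0)
    stop("`total_area` must be positive", call. = FALSE)
  if (!is.finite(target_area) || target_area <= 0)
    stop("`target_area` must be positive", call. = FALSE)
  ratio <- total_area / target_area
  k <- floor(ratio + 0.5)  # half away from zero (ratio > 0 here)
  max(1L, as.integer(k))
}

#' Spectral parcellation of a template surface
#'
#' Embeds every vertex by its coordinates in the low Laplace-Beltrami
#' eigenvectors and clusters the embedding with k-means. By default the k
#' non-constant eigenvectors with smallest eigenvalue are used (the
#' constant eigenvector carries no geometry; `include_trivial = TRUE`
#' reproduces the literal first-k reading). Disconnected label islands are
#' then reassigned to the neighbouring patch with the longest shared
#' boundary until every patch is edge-connected (`contiguity = FALSE`
#' disables this). Labels are canonicalized to descending patch area (ties
#' broken by the lowest contained vertex index) and are 0-based.
#'
#' @param mesh A connected `surface_mesh`.
#' @param k Number of patches, 1 <= k <= number of vertices.
#' @param seed Integer seed for k-means (k-means++-style multi-start via
#'   20 random restarts).
#' @param include_trivial Include the constant eigenvector in the
#'   embedding. Default `FALSE`.
#' @param mass_weighted Scale embedding rows by sqrt(vertex area).
#'   Default `FALSE`.
#' @param contiguity Repair disconnected patches. Default `TRUE`.
#' @param max_retries Reseeding attempts if k-means returns an empty
#'   cluster. Default 5.
#' @return An object of class `parcellation`: `labels` (0-based integer
#'   per vertex), `k`, `areas` (per-patch mm^2, by label), `seed`,
#'   `options`.
#' @export
spectral_parcellate <- function(mesh, k, seed = 1L, include_trivial = FALSE,
                                mass_weighted = FALSE, contiguity = TRUE,
                                max_retries = 5L) {
  validate_mesh(mesh)
  n <- n_vertices(mesh)
  if (k < 1 || k > n) stop("`k` must be in [1, ", n, "]", call. = FALSE)
  if (n_components(mesh) != 1L)
    stop("mesh must be connected for parcellation", call. = FALSE)
  va <- vertex_areas(mesh)
  if (k == 1L) {
    labels <- rep(0L, n)
    return(new_parcellation(labels, 1L, va, seed,
                            list(include_trivial = include_trivial,
                                 mass_weighted = mass_weighted,
                                 contiguity = contiguity)))
  }
  n_eig <- if (include_trivial) k else k + 1L
  eig <- lb_eigendecomposition(mesh, min(n_eig, n - 1L))
  emb <- if (include_trivial) eig$vectors[, seq_len(k), drop = FALSE]
         else eig$vectors[, -1L, drop = FALSE]
  if (mass_weighted) emb <- emb * sqrt(va)

  labels1 <- NULL
  for (attempt in 0:max_retries) {
    km <- with_seed(seed + attempt, stats::kmeans(emb, centers = k,
                                                  nstart = 20L,
                                                  iter.max = 200L))
    cand <- km$cluster
    if (contiguity) cand <- repair_contiguity(mesh, cand, k)
    if (length(unique(cand)) == k) { labels1 <- cand; break }
  }
  if (is.null(labels1))
    stop("k-means produced an empty patch after ", max_retries,
         " reseeding attempts", call. = FALSE)
  labels <- canonical_labels(labels1, va)
  new_parcellation(labels, as.integer(k), va, seed,
                   list(include_trivial = include_trivial,
                        mass_weighted = mass_weighted,
                        contiguity = contiguity))
}

new_parcellation <- function(labels0, k, vertex_area, seed, options) {
  areas <- as.numeric(rowsum(vertex_area, labels0))
  names(areas) <- sort(unique(labels0))
  structure(list(labels = labels0, k = k, areas = areas,
                 n_vertices = length(labels0), seed = seed,
                 options = options),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> k = %d over %d vertices; patch areas %.1f-%.1f mm^2\n",
              x$k, x$n_vertices, min(x$areas), max(x$areas)))
  invisible(x)
}

# relabel to 0..k-1 in descending area order, ties by lowest vertex index
canonical_labels <- function(labels1, vertex_area) {
  ids <- sort(unique(labels1))
  areas <- as.numeric(rowsum(vertex_area, labels1)[as.character(ids), 1L])
  firstv <- vapply(ids, function(id) min(which(labels1 == id)), integer(1))
  ord <- order(-areas, firstv)
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids) - 1L
  remap[labels1]
}

# reassign disconnected islands of each label to the adjacent patch with
# the longest shared boundary (summed edge length), iterated to convergence
repair_contiguity <- function(mesh, labels1, k, max_iter = 100L) {
  ed <- mesh_edges(mesh)
  elen <- sqrt(rowSums((mesh$vertices[ed[, 1L], , drop = FALSE] -
                          mesh$vertices[ed[, 2L], , drop = FALSE])^2))
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (lab in seq_len(k)) {
      vs <- which(labels1 == lab)
      if (length(vs) == 0L) next
      comp <- label_components(ed, labels1, lab, length(labels1))
      sizes <- table(comp[vs])
      if (length(sizes) <= 1L) next
      keep <- as.integer(names(which.max(sizes)))
      for (island in setdiff(as.integer(names(sizes)), keep)) {
        iv <- vs[comp[vs] == island]
        # boundary edges from the island to other labels
        on1 <- ed[, 1L] %in% iv; on2 <- ed[, 2L] %in% iv
        bnd <- xor(on1, on2)
        if (!any(bnd)) next
        other <- ifelse(on1[bnd], labels1[ed[bnd, 2L]], labels1[ed[bnd, 1L]])
        wl <- elen[bnd]
        keepout <- other != lab
        if (!any(keepout)) next
        tot <- tapply(wl[keepout], other[keepout], sum)
        labels1[iv] <- as.integer(names(which.max(tot)))
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels1
}

# connected components of the subgraph induced by one label
label_components <- function(ed, labels1, lab, n) {
  inlab <- labels1 == lab
  keep <- inlab[ed[, 1L]] & inlab[ed[, 2L]]
  sub <- ed[keep, , drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  adj <- split(c(sub[, 2L], sub[, 1L]), c(sub[, 1L], sub[, 2L]))
  for (s in which(inlab)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- nb
    }
  }
  comp
}

#' Patch means of a per-vertex field
#'
#' Unweighted arithmetic mean of the vertex values within each patch (the
#' averaging used to turn per-vertex expansion factors into patch
#' features); `area_weighted = TRUE` uses template vertex-area weights
#' instead.
#'
#' @param parc A `parcellation`.
#' @param field Numeric vector on the template vertices.
#' @param area_weighted Weight by template vertex areas. Default `FALSE`.
#' @param vertex_area Vertex areas, required if `area_weighted`.
#' @return Numeric vector of length k, named by 0-based patch label.
#' @export
patch_mean_features <- function(parc, field, area_weighted = FALSE,
                                vertex_area = NULL) {
  if (length(field) != parc$n_vertices)
    stop("field length ", length(field), " does not match template vertex count ",
         parc$n_vertices, call. = FALSE)
  if (area_weighted) {
    if (is.null(vertex_area)) stop("`vertex_area` required when area_weighted",
                                   call. = FALSE)
    num <- rowsum(field * vertex_area, parc$labels)
    den <- rowsum(vertex_area, parc$labels)
    out <- as.numeric(num / den)
  } else {
    out <- as.numeric(rowsum(field, parc$labels) /
                        tabulate(parc$labels + 1L, nbins = parc$k))
  }
  names(out) <- sort(unique(parc$labels))
  out
}

#' Write / read a parcellation
#'
#' CSV of (vertex_index, label), both 0-based, with a JSON sidecar
#' (`<path>.json`) recording k, per-patch areas, seed and options.
#'
#' @param parc A `parcellation`.
#' @param path CSV path.
#' @return `path` (write) or a `parcellation` (read).
#' @export
write_parcellation <- function(parc, path) {
  utils::write.csv(data.frame(vertex_index = seq_len(parc$n_vertices) - 1L,
                              label = parc$labels),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(k = parc$k, areas = as.numeric(parc$areas),
                            seed = parc$seed, options = parc$options),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- df$label[order(df$vertex_index)]
  structure(list(labels = as.integer(labels), k = as.integer(side$k),
                 areas = stats::setNames(as.numeric(side$areas),
                                         sort(unique(labels))),
                 n_vertices = length(labels),
                 seed = side$seed, options = side$options),
            class = "parcellation")
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
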