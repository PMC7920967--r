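#' Simulation specification for a synthetic cohort
#'
#' Defines the study conditions the generator emulates: a three-group
#' cohort (healthy comparison, lithium responders, non-responders; default
#' sizes 21/9/5), covariates drawn per group (age in years, sex with
#' female = 1, ICV in mm^3 — defaults match the study cohort's per-group
#' moments), a template surface per structure, smooth per-subject shape
#' noise, and one localized atrophy effect of configurable magnitude
#' (default 15% in one patch of non-responders).
#'
#' @param structure `"icosphere"`, `"ellipsoid"` or `"bent_tube"`.
#' @param geometry List of geometry parameters passed to the template
#'   builder (see [icosphere()], [ellipsoid_mesh()], [bent_tube_mesh()]).
#' @param n_hc,n_r,n_nr Group sizes (default 21, 9, 5).
#' @param age_mean,age_sd Per-group age moments, years (HC, R, NR).
#' @param sex_p_female Per-group probability of female.
#' @param icv_mean,icv_sd Per-group ICV moments, mm^3.
#' @param effect_patch 0-based target patch of the atrophy effect.
#' @param atrophy Atrophy fraction a in [0, 1); target-patch area of
#'   non-responders shrinks by factor (1 - a). Default 0.15.
#' @param coef Feature-model coefficients: intercept, age, sex, icv
#'   (per-unit effects on the expansion factor).
#' @param noise_amplitude Mesh mode: sd (mm) of the smooth low-frequency
#'   normal-displacement noise.
#' @param feature_sd Feature mode: Gaussian sd on patch features.
#' @param n_patches Feature mode: number of patches (default 9,
#'   hippocampus-scale).
#' @param target_area Patch-size rule target (mm^2), mesh mode.
#' @param seed Integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(structure = c("icosphere", "ellipsoid", "bent_tube"),
                            geometry = list(),
                            n_hc = 21L, n_r = 9L, n_nr = 5L,
                            age_mean = c(HC = 36.3, R = 37.7, NR = 31.0),
                            age_sd = c(HC = 13.0, R = 15.2, NR = 9.8),
                            sex_p_female = c(HC = 0.71, R = 0.78, NR = 1.0),
                            icv_mean = c(HC = 1503e3, R = 1472e3, NR = 1406e3),
                            icv_sd = c(HC = 132e3, R = 134e3, NR = 34e3),
                            effect_patch = 0L, atrophy = 0.15,
                            coef = c(intercept = 1, age = -0.002,
                                     sex = 0.02, icv = 5e-8),
                            noise_amplitude = 0.1, feature_sd = 0.05,
                            n_patches = 9L, target_area = 150,
                            seed = 1L) {
  structure_kind <- match.arg(structure)
  if (atrophy < 0 || atrophy >= 1) stop("`atrophy` must be in [0, 1)", call. = FALSE)
  if (feature_sd < 0 || noise_amplitude < 0) stop("noise must be >= 0", call. = FALSE)
  if (n_hc < 0 || n_r < 0 || n_nr < 0 || n_hc + n_r + n_nr < 2)
    stop("need non-negative group sizes totalling >= 2", call. = FALSE)
  structure(list(structure = structure_kind, geometry = geometry,
                 n_hc = as.integer(n_hc), n_r = as.integer(n_r),
                 n_nr = as.integer(n_nr),
                 age_mean = age_mean, age_sd = age_sd,
                 sex_p_female = sex_p_female,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 effect_patch = as.integer(effect_patch), atrophy = atrophy,
                 coef = coef, noise_amplitude = noise_amplitude,
                 feature_sd = feature_sd, n_patches = as.integer(n_patches),
                 target_area = target_area, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %s; groups %d/%d/%d; atrophy %.0f%% at patch %d\n",
              x$structure, x$n_hc, x$n_r, x$n_nr, 100 * x$atrophy,
              x$effect_patch))
  invisible(x)
}

#' Template mesh for a simulation spec
#' @param spec A `simulation_spec`.
#' @return A `surface_mesh`.
#' @export
make_template_mesh <- function(spec) {
  g <- spec$geometry
  switch(spec$structure,
    icosphere = icosphere(radius = g$radius %||% 10.37,
                          subdivisions = g$subdivisions %||% 3L),
    ellipsoid = ellipsoid_mesh(semi_axes = g$semi_axes %||% c(17, 8, 7),
                               subdivisions = g$subdivisions %||% 4L),
    bent_tube = bent_tube_mesh(arc_radius = g$arc_radius %||% 16,
                               tube_radius = g$tube_radius %||% 5,
                               arc_angle = g$arc_angle %||% 2.2,
                               n_u = g$n_u %||% 24L, n_v = g$n_v %||% 16L))
}

#' Simulate a covariate table
#'
#' Draws age, sex and ICV per group from the spec's per-group
#' distributions; subjects are ordered HC, R, NR with ids `s001`, ...
#' `group_long` duplicates `group` (a second response timepoint with the
#' same labels) unless `n_long_switch` responders are relabelled NR.
#'
#' @param spec A `simulation_spec`.
#' @param n_long_switch Responders relabelled NR at the long timepoint.
#' @return Covariate tibble (id, age, sex, icv, group, group_long).
#' @export
simulate_covariates <- function(spec, n_long_switch = 0L) {
  groups <- rep(c("HC", "R", "NR"), c(spec$n_hc, spec$n_r, spec$n_nr))
  n <- length(groups)
  age <- stats::rnorm(n, spec$age_mean[groups], spec$age_sd[groups])
  age <- pmax(age, 18)
  # every modeled covariate needs >= 2 distinct values inside each contrast
  # subset; with an all-female NR group the sex draw can degenerate, so
  # redraw until both contrast subsets contain both sexes
  in_bd <- groups %in% c("R", "NR")
  for (try in 1:100) {
    sex <- stats::rbinom(n, 1L, spec$sex_p_female[groups])
    ok <- (!any(in_bd) || length(unique(sex[in_bd])) > 1L) &&
      length(unique(sex)) > 1L
    if (ok) break
  }
  if (!ok) stop("could not draw a non-degenerate sex covariate", call. = FALSE)
  icv <- stats::rnorm(n, spec$icv_mean[groups], spec$icv_sd[groups])
  group_long <- groups
  if (n_long_switch > 0L) {
    r_idx <- which(groups == "R")
    group_long[r_idx[seq_len(min(n_long_switch, length(r_idx)))]] <- "NR"
  }
  tibble::tibble(id = sprintf("s%03d", seq_len(n)), age = age, sex = sex,
                 icv = icv, group = groups, group_long = group_long)
}

#' Simulate one subject mesh from the template
#'
#' Displaces template vertices by (i) a global isotropic scale driven by
#' the subject's ICV relative to the cohort reference (linear dimensions
#' scale as the cube root of volume), (ii) smooth low-frequency noise
#' along vertex normals (a random combination of the first few
#' non-constant Laplace-Beltrami eigenfunctions, each normalized to unit
#' maximum), and (iii) for non-responders, an inward displacement on the
#' target patch calibrated so the patch's mean vertex-area expansion
#' factor equals (1 - atrophy).
#'
#' @param template Template `surface_mesh`.
#' @param parc `parcellation` of the template (locates the target patch).
#' @param spec A `simulation_spec`.
#' @param covariates One-row covariate data frame for this subject.
#' @param basis Precomputed noise basis from [lb_noise_basis()] (computed
#'   on the fly if `NULL`).
#' @param icv_ref Reference ICV (mm^3); defaults to the spec's pooled
#'   mean.
#' @return A `surface_mesh` with the template's topology.
#' @export
simulate_subject_mesh <- function(template, parc, spec, covariates,
                                  basis = NULL, icv_ref = NULL) {
  if (is.null(basis)) basis <- lb_noise_basis(template)
  if (is.null(icv_ref)) icv_ref <- pooled_icv_mean(spec)
  scale <- (covariates$icv / icv_ref)^(1 / 3)
  ctr <- colMeans(template$vertices)
  v <- sweep(sweep(template$vertices, 2L, ctr), 1L, scale, "*")
  v <- sweep(v, 2L, ctr, "+")
  mesh <- surface_mesh(v, template$faces, validate = FALSE)
  if (spec$noise_amplitude > 0) {
    coefs <- stats::rnorm(ncol(basis), 0, spec$noise_amplitude)
    disp <- as.numeric(basis %*% coefs)
    mesh$vertices <- mesh$vertices + vertex_normals(mesh) * disp
  }
  if (spec$atrophy > 0 &&
      as.character(covariates$group) == "NR") {
    mesh <- apply_patch_atrophy(mesh, parc, spec$effect_patch, spec$atrophy)
  }
  mesh
}

pooled_icv_mean <- function(spec) {
  w <- c(spec$n_hc, spec$n_r, spec$n_nr)
  if (sum(w) == 0) return(mean(spec$icv_mean))
  sum(spec$icv_mean * w) / sum(w)
}

#' Low-frequency Laplace-Beltrami noise basis
#'
#' The first `n_modes` non-constant eigenfunctions of the template's
#' Laplace-Beltrami operator, each scaled to unit maximum absolute value,
#' as columns. Random coefficients on these columns give smooth,
#' anatomically plausible shape noise that preserves vertex
#' correspondence.
#'
#' @param template Template `surface_mesh`.
#' @param n_modes Number of modes (default 6).
#' @return n_vertices x n_modes matrix.
#' @export
lb_noise_basis <- function(template, n_modes = 6L) {
  eig <- lb_eigendecomposition(template, n_modes + 1L)
  basis <- eig$vectors[, -1L, drop = FALSE]
  sweep(basis, 2L, apply(abs(basis), 2L, max), "/")
}

# inward normal displacement on the target patch, magnitude solved so the
# patch mean vertex-area ratio hits (1 - atrophy); only interior patch
# vertices move (zero displacement on the patch boundary), so vertex areas
# outside the patch are untouched
apply_patch_atrophy <- function(mesh, parc, patch, atrophy) {
  in_patch <- parc$labels == patch
  if (!any(in_patch)) stop("target patch ", patch, " is empty", call. = FALSE)
  # ramp the displacement up over the first rings inside the patch so the
  # wall shared with neighbouring patches stays nearly unstretched
  d <- ring_depth(mesh, in_patch, max_depth = 3L)
  w <- pmin(d, 3L) / 3
  va0 <- vertex_areas(mesh)
  # contract vertices toward the patch centroid (which lies just beneath a
  # curved patch), so triangles shrink tangentially and the patch loses
  # area without denting a wall into the neighbours
  ctr <- colMeans(mesh$vertices[in_patch, , drop = FALSE])
  displaced <- function(s) {
    off <- sweep(mesh$vertices, 2L, ctr)
    mesh$vertices - (s * w) * off
  }
  patch_ratio <- function(s) {
    m2 <- surface_mesh(displaced(s), mesh$faces, validate = FALSE)
    mean(vertex_areas(m2)[in_patch] / va0[in_patch])
  }
  f <- function(s) patch_ratio(s) - (1 - atrophy)
  if (f(0.9) > 0)
    stop("could not calibrate the patch atrophy displacement", call. = FALSE)
  s_star <- stats::uniroot(f, c(0, 0.9), tol = 1e-9)$root
  surface_mesh(displaced(s_star), mesh$faces, validate = FALSE)
}

# graph-distance depth into a vertex subset: 0 outside, 1 on the subset's
# boundary ring, increasing inwards (BFS from the complement), capped at
# max_depth
ring_depth <- function(mesh, in_set, max_depth = 3L) {
  ed <- mesh_edges(mesh)
  adj <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
  n <- length(in_set)
  d <- ifelse(in_set, NA_integer_, 0L)
  frontier <- which(!in_set)
  level <- 0L
  while (length(frontier) && anyNA(d) && level < max_depth) {
    level <- level + 1L
    nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nb <- nb[is.na(d[nb])]
    d[nb] <- level
    frontier <- nb
  }
  d[is.na(d)] <- max_depth
  d
}

#' Simulate a feature-level cohort
#'
#' Draws the patches x subjects feature matrix directly from the linear
#' model the analysis assumes: Y(p, i) = intercept + b_age age_i +
#' b_sex sex_i + b_icv icv_i + b_response 1{i is NR, p is target} +
#' Gaussian noise, with b_response = -atrophy. The ground truth (target
#' patch, coefficients, seed) is returned alongside.
#'
#' @param spec A `simulation_spec`.
#' @return List with `features` (k x n matrix), `covariates` (tibble) and
#'   `truth` (list: effect_patch, beta, seed).
#' @export
simulate_feature_matrix <- function(spec) {
  with_seed(spec$seed, {
    cov <- simulate_covariates(spec)
    n <- nrow(cov)
    k <- spec$n_patches
    base <- spec$coef[["intercept"]] + spec$coef[["age"]] * cov$age +
      spec$coef[["sex"]] * cov$sex + spec$coef[["icv"]] * cov$icv
    Y <- matrix(rep(base, each = k), nrow = k)
    b_resp <- -spec$atrophy
    is_nr <- cov$group == "NR"
    Y[spec$effect_patch + 1L, is_nr] <- Y[spec$effect_patch + 1L, is_nr] + b_resp
    if (spec$feature_sd > 0)
      Y <- Y + matrix(stats::rnorm(k * n, 0, spec$feature_sd), k, n)
    dimnames(Y) <- list(paste0("patch_", seq_len(k) - 1L), cov$id)
    list(features = Y, covariates = cov,
         truth = list(effect_patch = spec$effect_patch,
                      beta = c(spec$coef, response = b_resp),
                      seed = spec$seed))
  })
}

#' Simulate a full cohort
#'
#' `mode = "feature"` delegates to [simulate_feature_matrix()].
#' `mode = "mesh"` builds the template, parcellates it under the
#' average-patch-area rule, and generates one subject mesh per row of the
#' covariate table (non-responders carry the calibrated target-patch
#' atrophy). All randomness derives from `spec$seed`; identical specs
#' give identical cohorts.
#'
#' @param spec A `simulation_spec`.
#' @param mode `"feature"` or `"mesh"`.
#' @return Feature mode: see [simulate_feature_matrix()]. Mesh mode: list
#'   with `template`, `parcellation`, `meshes` (named list),
#'   `covariates`, `truth`.
#' @export
simulate_cohort <- function(spec, mode = c("feature", "mesh")) {
  mode <- match.arg(mode)
  if (mode == "feature") return(simulate_feature_matrix(spec))
  template <- make_template_mesh(spec)
  k <- choose_patch_count(surface_area(template), spec$target_area)
  parc <- spectral_parcellate(template, k, seed = spec$seed)
  basis <- lb_noise_basis(template)
  icv_ref <- pooled_icv_mean(spec)
  with_seed(spec$seed, {
    cov <- simulate_covariates(spec)
    meshes <- vector("list", nrow(cov))
    for (i in seq_len(nrow(cov))) {
      meshes[[i]] <- simulate_subject_mesh(template, parc, spec,
                                           cov[i, ], basis = basis,
                                           icv_ref = icv_ref)
    }
    names(meshes) <- cov$id
    list(template = template, parcellation = parc, meshes = meshes,
         covariates = cov,
         truth = list(effect_patch = spec$effect_patch,
                      atrophy = spec$atrophy, k = k, seed = spec$seed))
  })
}
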