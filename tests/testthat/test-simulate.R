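test_that("template geometries hit their analytic areas", {
  sph <- make_template_mesh(simulation_spec("icosphere",
                                            geometry = list(radius = 10.37,
                                                            subdivisions = 3)))
  target <- 4 * pi * 10.37^2
  expect_lt(abs(surface_area(sph) - target) / target, 0.02)

  ell <- make_template_mesh(simulation_spec("ellipsoid",
                                            geometry = list(semi_axes = c(17, 8, 7))))
  thom <- ellipsoid_area_thomsen(c(17, 8, 7))
  expect_lt(abs(surface_area(ell) - thom) / thom, 0.02)

  tube <- make_template_mesh(simulation_spec("bent_tube"))
  validate_mesh(tube, require_connected = TRUE)
  expect_gt(mesh_volume(tube), 0)
})

test_that("covariate tables honour the group design", {
  spec <- simulation_spec(seed = 1)
  cov <- with_seed(1, simulate_covariates(spec))
  expect_identical(nrow(cov), 35L)
  expect_identical(sum(cov$group == "HC"), 21L)
  expect_identical(sum(cov$group == "R"), 9L)
  expect_identical(sum(cov$group == "NR"), 5L)
  expect_true(all(cov$sex[cov$group == "NR"] == 1))   # all-female NR group
  expect_true(all(cov$sex %in% c(0, 1)))
  validate_covariates(cov)
  cov2 <- with_seed(1, simulate_covariates(spec, n_long_switch = 2))
  expect_identical(sum(cov2$group_long == "NR"), 7L)
})

test_that("subject meshes reduce to the template when nothing varies", {
  spec <- simulation_spec("icosphere", geometry = list(radius = 8,
                                                       subdivisions = 2),
                          noise_amplitude = 0, atrophy = 0)
  template <- make_template_mesh(spec)
  parc <- spectral_parcellate(template, 4, seed = 1)
  covrow <- tibble::tibble(id = "x", age = 30, sex = 1,
                           icv = patchmorph:::pooled_icv_mean(spec),
                           group = "NR")
  m <- simulate_subject_mesh(template, parc, spec, covrow)
  expect_equal(m$vertices, template$vertices, tolerance = 1e-12)
})

test_that("calibrated atrophy shows up only in the target patch", {
  spec <- simulation_spec("icosphere", geometry = list(radius = 10.37,
                                                       subdivisions = 3),
                          noise_amplitude = 0, atrophy = 0.15,
                          effect_patch = 2L)
  template <- make_template_mesh(spec)
  parc <- spectral_parcellate(template, 9, seed = 3)
  covrow <- tibble::tibble(id = "x", age = 30, sex = 1,
                           icv = patchmorph:::pooled_icv_mean(spec),
                           group = "NR")
  m <- simulate_subject_mesh(template, parc, spec, covrow)
  means <- patch_mean_features(parc, surface_jacobian(template, m))
  expect_lt(abs(means[["2"]] - 0.85), 0.02 * 0.85)
  others <- means[names(means) != "2"]
  expect_lt(max(abs(others - 1)), 0.02)
})

test_that("feature simulation realizes the stated linear model", {
  flat <- simulate_feature_matrix(
    simulation_spec(atrophy = 0, feature_sd = 0,
                    coef = c(intercept = 1, age = 0, sex = 0, icv = 0)))
  expect_true(all(flat$features == 1))

  eff <- simulate_feature_matrix(
    simulation_spec(atrophy = 0.15, feature_sd = 0,
                    coef = c(intercept = 1, age = 0, sex = 0, icv = 0),
                    effect_patch = 4L))
  nr <- eff$covariates$group == "NR"
  expect_true(all(abs(eff$features[5, nr] - 0.85) < 1e-12))
  expect_true(all(abs(eff$features[-5, ] - 1) < 1e-12))
  expect_equal(eff$truth$beta[["response"]], -0.15)

  # with noise, OLS recovers the response coefficient within 3 SE
  noisy <- simulate_feature_matrix(simulation_spec(atrophy = 0.15,
                                                   feature_sd = 0.05,
                                                   seed = 33))
  X <- build_design(noisy$covariates, "NR_vs_HCandR", TRUE)
  fit <- fit_glm(noisy$features, X)
  p <- noisy$truth$effect_patch + 1L
  se <- sqrt(fit$sse[p] / fit$df_residual *
               solve(crossprod(X))["response", "response"])
  expect_lt(abs(fit$coefficients["response", p] - (-0.15)), 3 * se)
})

test_that("cohorts are reproducible from the seed alone", {
  spec <- simulation_spec(seed = 12)
  a <- simulate_feature_matrix(spec)
  b <- simulate_feature_matrix(spec)
  expect_identical(a$features, b$features)
  expect_identical(a$covariates, b$covariates)

  mspec <- simulation_spec("icosphere", geometry = list(radius = 6.91,
                                                        subdivisions = 2),
                           n_hc = 3, n_r = 2, n_nr = 2,
                           noise_amplitude = 0.05, seed = 9)
  c1 <- simulate_cohort(mspec, mode = "mesh")
  c2 <- simulate_cohort(mspec, mode = "mesh")
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(c1$meshes[["s005"]]$vertices, c2$meshes[["s005"]]$vertices)
  expect_identical(c1$parcellation$labels, c2$parcellation$labels)
})

test_that("mesh-mode cohorts recover the injected deficit through the pipeline", {
  spec <- simulation_spec("icosphere", geometry = list(radius = 10.37,
                                                       subdivisions = 3),
                          noise_amplitude = 0.02, atrophy = 0.15, seed = 14)
  cohort <- simulate_cohort(spec, mode = "mesh")
  expect_identical(cohort$truth$k, 9L)
  fields <- lapply(cohort$meshes,
                   function(m) surface_jacobian(cohort$template, m))
  Y <- assemble_feature_matrix(cohort$parcellation, fields,
                               cohort$covariates$id)
  # normalize away the global ICV scale before comparing to the target
  nr <- cohort$covariates$group == "NR"
  tgt <- cohort$truth$effect_patch + 1L
  rel_nr <- mean(Y[tgt, nr] / colMeans(Y[-tgt, nr, drop = FALSE]))
  rel_other <- mean(Y[tgt, !nr] / colMeans(Y[-tgt, !nr, drop = FALSE]))
  deficit <- 1 - rel_nr / rel_other
  expect_lt(abs(deficit - 0.15), 0.03)
})
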