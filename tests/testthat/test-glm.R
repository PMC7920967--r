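test_that("design matrices implement the two contrasts", {
  spec <- simulation_spec(seed = 8)
  cov <- simulate_feature_matrix(spec)$covariates
  X1 <- build_design(cov, "NR_vs_R", TRUE)
  expect_identical(dim(X1), c(14L, 5L))
  expect_identical(colnames(X1),
                   c("(Intercept)", "age", "sex", "icv", "response"))
  expect_equal(sum(X1[, "response"]), 5)
  X2 <- build_design(cov, "NR_vs_HCandR", TRUE)
  expect_identical(dim(X2), c(35L, 5L))
  expect_equal(sum(X2[, "response"]), 5)
  X3 <- build_design(cov, "NR_vs_R", FALSE)
  expect_identical(ncol(X3), 4L)

  allf <- cov
  allf$sex <- 1
  expect_error(build_design(allf, "NR_vs_R"), "sex")
  badgrp <- cov; badgrp$group[1] <- "patient"
  expect_error(build_design(badgrp), "unknown group")
})

test_that("OLS fits match the normal-equations oracle", {
  set.seed(21)
  cov <- tiny_covariates(n_r = 6, n_nr = 6)
  X <- build_design(cov, "NR_vs_R", TRUE)
  Y <- matrix(rnorm(4 * 12, 1, 0.2), 4, 12,
              dimnames = list(paste0("patch_", 0:3), cov$id))
  fit <- fit_glm(Y, X)
  # independent oracle: solve normal equations per patch on scaled columns
  for (p in 1:4) {
    beta <- solve(crossprod(X), crossprod(X, Y[p, ]))
    expect_equal(unname(fit$coefficients[, p]), as.numeric(beta),
                 tolerance = 1e-6)
    expect_equal(fit$sse[[p]], sum((Y[p, ] - X %*% beta)^2), tolerance = 1e-9)
  }
  expect_identical(fit$df_residual, 7L)
  td <- tidy(fit)
  expect_identical(nrow(td), 20L)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("exact linear data gives zero SSE and recovered coefficients", {
  cov <- tiny_covariates(n_r = 5, n_nr = 5)
  X <- build_design(cov, "NR_vs_R", TRUE)
  beta <- c(1, -0.002, 0.02, 5e-8, -0.15)
  Y <- matrix(as.numeric(X %*% beta), 1, 10,
              dimnames = list("patch_0", cov$id))
  fit <- fit_glm(Y, X)
  expect_lt(fit$sse[[1]], 1e-18)
  expect_equal(unname(fit$coefficients[, 1]), beta, tolerance = 1e-7)

  # intercept-only design: SSE is the centered sum of squares
  X0 <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  attr(X0, "subjects") <- cov$id
  fit0 <- fit_glm(Y, X0)
  expect_equal(fit0$sse[[1]], sum((Y[1, ] - mean(Y[1, ]))^2), tolerance = 1e-12)

  expect_error(fit_glm(Y[, 1:3, drop = FALSE], X), "lacks subject")
})

contrast_match <- function(cov, contrast) {
  if (contrast == "NR_vs_R") cov$group %in% c("R", "NR") else rep(TRUE, nrow(cov))
}

test_that("s_p equals 1 + F/(n - 5) against an independent partial-F oracle", {
  set.seed(77)
  spec <- simulation_spec(atrophy = 0.15, feature_sd = 0.05, seed = 19)
  sim <- simulate_feature_matrix(spec)
  for (contrast in c("NR_vs_R", "NR_vs_HCandR")) {
    sr <- sse_ratio(sim$features, sim$covariates, contrast)
    X <- build_design(sim$covariates, contrast, TRUE)
    n <- nrow(X)
    keep <- contrast_match(sim$covariates, contrast)
    for (p in seq_len(nrow(sim$features))) {
      df <- data.frame(y = sim$features[p, keep],
                       age = sim$covariates$age[keep],
                       sex = sim$covariates$sex[keep],
                       icv = sim$covariates$icv[keep],
                       response = as.numeric(sim$covariates$group[keep] == "NR"))
      f_alt <- lm(y ~ age + sex + icv + response, df)
      f_null <- lm(y ~ age + sex + icv, df)
      Fstat <- anova(f_null, f_alt)$F[2]
      expect_equal(sr$s_p[p], 1 + Fstat / (n - 5), tolerance = 1e-9)
    }
  }
})

test_that("s_p >= 1 and is invariant to affine rescaling of features", {
  sim <- null_cohort(5)
  s0 <- sse_ratio(sim$features, sim$covariates)$s_p
  expect_true(all(s0 >= 1))
  rescaled <- sweep(sweep(sim$features, 1, runif(9, 0.5, 2), "*"),
                    1, rnorm(9), "+")
  s1 <- sse_ratio(rescaled, sim$covariates)$s_p
  expect_equal(s1, s0, tolerance = 1e-9)
})

test_that("noise orthogonal to the response direction gives s_p of one", {
  cov <- tiny_covariates(n_r = 5, n_nr = 5)
  X_alt <- build_design(cov, "NR_vs_R", TRUE)
  X_null <- build_design(cov, "NR_vs_R", FALSE)
  # residualize the response column against the null design, then build
  # noise orthogonal to it: SSE_null == SSE_alt exactly
  r <- resid(lm(X_alt[, "response"] ~ X_null - 1))
  set.seed(4)
  noise <- rnorm(10)
  noise <- noise - sum(noise * r) / sum(r * r) * r
  Y <- matrix(as.numeric(X_null %*% c(1, 0.01, 0.02, 1e-8)) + noise, 1, 10,
              dimnames = list("patch_0", cov$id))
  s <- sse_ratio(Y, cov, "NR_vs_R")$s_p
  expect_equal(s, 1, tolerance = 1e-9)
})

test_that("a perfect alternative fit yields infinite s_p with a warning", {
  cov <- tiny_covariates(n_r = 3, n_nr = 2)
  X_alt <- build_design(cov, "NR_vs_R", TRUE)
  Y <- matrix(as.numeric(X_alt %*% c(1, 0, 0, 0, -0.2)), 1, 5,
              dimnames = list("patch_0", cov$id))
  expect_warning(s <- sse_ratio(Y, cov, "NR_vs_R")$s_p, "perfect")
  expect_identical(s, Inf)
})
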