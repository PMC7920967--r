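# In-code fixtures shared across test files.

# Closed unit cube: 8 vertices, 12 outward-wound triangles.
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # z = 0
             c(5, 6, 7), c(5, 7, 8),   # z = 1
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 4, 8), c(3, 8, 7),   # y = 1
             c(1, 5, 8), c(1, 8, 4),   # x = 0
             c(2, 3, 7), c(2, 7, 6))   # x = 1
  surface_mesh(v, f)
}

single_triangle_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3)), validate = FALSE)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

# small hand-made covariate table with both groups and sex variation
tiny_covariates <- function(n_r = 3L, n_nr = 3L, n_hc = 0L, seed = 42L) {
  set.seed(seed)
  groups <- rep(c("HC", "R", "NR"), c(n_hc, n_r, n_nr))
  n <- length(groups)
  tibble::tibble(
    id = sprintf("t%02d", seq_len(n)),
    age = round(runif(n, 20, 60), 1),
    sex = rep_len(c(0, 1), n),
    icv = round(rnorm(n, 1.5e6, 1e5)),
    group = groups)
}

# feature-level null cohort at the study design (21 HC / 9 R / 5 NR)
null_cohort <- function(seed, sd = 0.05) {
  simulate_feature_matrix(simulation_spec(atrophy = 0, feature_sd = sd,
                                          seed = seed))
}

# independent exhaustive oracle on a tiny cohort: loop every permutation,
# refit both models with lm(), take the max statistic across patches
exhaustive_oracle <- function(Y, cov, contrast = "NR_vs_R") {
  keep <- if (contrast == "NR_vs_R") cov$group %in% c("R", "NR")
          else rep(TRUE, nrow(cov))
  sub <- cov[keep, ]
  Ys <- Y[, sub$id, drop = FALSE]
  n <- ncol(Ys)
  stat_of <- function(Ymat) {
    vapply(seq_len(nrow(Ymat)), function(p) {
      d <- data.frame(y = Ymat[p, ], age = sub$age, sex = sub$sex,
                      icv = sub$icv, resp = as.numeric(sub$group == "NR"))
      sum(resid(lm(y ~ age + sex + icv, d))^2) /
        sum(resid(lm(y ~ age + sex + icv + resp, d))^2)
    }, numeric(1))
  }
  s_obs <- stat_of(Ys)
  perms <- gtools_perms(n)
  maxs <- apply(perms, 1, function(pm) max(stat_of(Ys[, pm, drop = FALSE])))
  p_adj <- vapply(s_obs, function(s) (1 + sum(maxs >= s)) / (1 + length(maxs)),
                  numeric(1))
  list(s = s_obs, p = p_adj)
}

# iterative heap-style permutation enumeration, independent of the package
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(row) append(row, n, after = pos - 1)))
  }))
}

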