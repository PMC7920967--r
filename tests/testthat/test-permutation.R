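test_that("Monte-Carlo run at n_perm >= n! matches the exhaustive oracle exactly", {
  set.seed(13)
  cov <- tiny_covariates(n_r = 3, n_nr = 3)
  Y <- matrix(rnorm(12, 1, 0.1), 2, 6,
              dimnames = list(c("patch_0", "patch_1"), cov$id))
  expect_message(
    pr <- max_stat_permutation(Y, cov, "NR_vs_R", n_perm = 720, seed = 1),
    "exhaustively")
  expect_true(pr$exhaustive)
  expect_identical(pr$n_perm, 720L)
  oracle <- exhaustive_oracle(Y, cov)
  expect_equal(pr$table$s_p, oracle$s, tolerance = 1e-9)
  expect_equal(pr$table$p_adj, oracle$p, tolerance = 1e-12)
})

test_that("an overwhelming injected effect saturates at the smallest p", {
  spec <- simulation_spec(atrophy = 0.9, feature_sd = 0.01, seed = 6,
                          effect_patch = 3L)
  sim <- simulate_feature_matrix(spec)
  pr <- max_stat_permutation(sim$features, sim$covariates, "NR_vs_R",
                             n_perm = 500, seed = 2)
  expect_true(pr$table$significant[pr$table$patch == 3])
  expect_equal(pr$table$p_adj[pr$table$patch == 3], 1 / 501)
  expect_identical(which.max(pr$table$s_p), 4L)
})

test_that("adjusted p-values are monotone in s_p and flags match the critical value", {
  sim <- null_cohort(31)
  pr <- max_stat_permutation(sim$features, sim$covariates, "NR_vs_R",
                             n_perm = 400, seed = 9)
  tab <- pr$table[order(pr$table$s_p), ]
  expect_true(all(diff(tab$p_adj) <= 1e-12))
  expect_true(all(tab$p_adj >= 1 / 401 & tab$p_adj <= 1))
  expect_identical(tab$significant, tab$s_p > pr$critical)
  expect_identical(tab$significant, tab$p_adj < 0.05)
})

test_that("permutation runs are reproducible and schemes both run", {
  sim <- null_cohort(17)
  a <- max_stat_permutation(sim$features, sim$covariates, n_perm = 200, seed = 3)
  b <- max_stat_permutation(sim$features, sim$covariates, n_perm = 200, seed = 3)
  expect_identical(a$table, b$table)
  expect_identical(a$max_dist, b$max_dist)
  fl <- max_stat_permutation(sim$features, sim$covariates, n_perm = 200,
                             seed = 3, scheme = "freedman_lane")
  expect_equal(fl$table$s_p, a$table$s_p)   # observed statistic is scheme-free
  expect_false(identical(fl$max_dist, a$max_dist))
})

test_that("percent atrophy recovers the injected deficit on noise-free features", {
  spec <- simulation_spec(atrophy = 0.15, feature_sd = 0,
                          coef = c(intercept = 1, age = 0, sex = 0, icv = 0),
                          seed = 2)
  sim <- simulate_feature_matrix(spec)
  expect_equal(percent_atrophy(sim$features, sim$covariates, 0, "NR_vs_R"), 15,
               tolerance = 1e-9)
  expect_equal(percent_atrophy(sim$features, sim$covariates, 0, "NR_vs_HCandR"),
               15, tolerance = 1e-9)
  expect_equal(percent_atrophy(sim$features, sim$covariates, 1, "NR_vs_R"), 0,
               tolerance = 1e-9)
})

test_that("contrast report flags only the structure carrying the effect", {
  eff <- simulate_feature_matrix(
    simulation_spec(atrophy = 0.3, feature_sd = 0.04, seed = 41))
  nul <- simulate_feature_matrix(
    simulation_spec(atrophy = 0, feature_sd = 0.04, seed = 42))
  rep_tbl <- report_contrasts(
    list(left_hippocampus = eff$features, right_hippocampus = nul$features),
    eff$covariates, contrasts = "NR_vs_R",
    timepoints = c(acute = "group"), n_perm = 400, seed = 7)
  expect_identical(nrow(rep_tbl), 2L)
  lh <- rep_tbl[rep_tbl$structure == "left_hippocampus", ]
  rh <- rep_tbl[rep_tbl$structure == "right_hippocampus", ]
  expect_lt(lh$min_p_adj, 0.05)
  expect_identical(lh$best_patch, eff$truth$effect_patch)
  expect_gt(rh$min_p_adj, 0.05)

  # identical feature matrices give identical rows apart from the label
  rep_same <- report_contrasts(
    list(a = eff$features, b = eff$features), eff$covariates,
    contrasts = "NR_vs_R", timepoints = c(acute = "group"),
    n_perm = 300, seed = 5)
  expect_equal(rep_same$min_p_adj[1], rep_same$min_p_adj[2])

  # both timepoints are reported when a long-term label column exists
  rep_tp <- report_contrasts(list(a = eff$features), eff$covariates,
                             contrasts = "NR_vs_R",
                             timepoints = c(acute = "group", long = "group_long"),
                             n_perm = 300, seed = 5)
  expect_setequal(rep_tp$timepoint, c("acute", "long"))
})
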