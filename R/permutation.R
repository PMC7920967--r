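#' Max-statistic permutation test with familywise error control
#'
#' Computes the observed SSE-ratio statistic s_p per patch, then builds
#' the permutation distribution of the maximum statistic across patches.
#' Each permutation rearranges the feature vectors among the subjects
#' (`scheme = "shuffle_features"`, the default: whole columns of Y are
#' permuted against the fixed design) or permutes null-model residuals
#' (`scheme = "freedman_lane"`, which preserves the covariate fit and
#' permutes only what the response could explain). Adjusted p-values use
#' the (1 + b) / (1 + B) convention; a patch is significant when its
#' statistic exceeds the 95th percentile of the max-statistic
#' distribution, i.e. when its adjusted p is below `alpha`.
#'
#' When the subjects admit no more than `n_perm` distinct rearrangements
#' (n! <= n_perm), all permutations are enumerated exhaustively (with a
#' message) instead of sampled.
#'
#' @param Y Feature matrix, patches x subjects.
#' @param cov Covariate table.
#' @param contrast `"NR_vs_R"` or `"NR_vs_HCandR"`.
#' @param n_perm Number of permutations (>= 100), default 10000.
#' @param seed Integer RNG seed.
#' @param scheme `"shuffle_features"` or `"freedman_lane"`.
#' @param alpha Familywise level, default 0.05.
#' @param group_col Response-label column for the timepoint tested.
#' @return Object of class `perm_result`; see [tidy.perm_result()] and
#'   [glance.perm_result()].
#' @export
max_stat_permutation <- function(Y, cov, contrast = "NR_vs_R",
                                 n_perm = 10000L, seed = 1L,
                                 scheme = c("shuffle_features", "freedman_lane"),
                                 alpha = 0.05, group_col = "group") {
  scheme <- match.arg(scheme)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  X_alt <- build_design(cov, contrast, TRUE, group_col)
  X_null <- build_design(cov, contrast, FALSE, group_col)
  Y <- align_features(Y, X_alt)
  n <- ncol(Y)
  Qn <- proj_residual(X_null)
  Qa <- proj_residual(X_alt)
  s_obs <- sse_ratio_stat(Y, Qn, Qa)

  exhaustive <- factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    message("only ", nrow(perms), " distinct permutations of ", n,
            " subjects; enumerating exhaustively")
  } else {
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  B <- nrow(perms)

  if (scheme == "freedman_lane") {
    fit0 <- Y %*% (diag(n) - Qn)   # null-model fitted values
    res0 <- Y %*% Qn
  }
  max_dist <- numeric(B)
  for (b in seq_len(B)) {
    pm <- perms[b, ]
    Yp <- if (scheme == "shuffle_features") Y[, pm, drop = FALSE]
          else fit0 + res0[, pm, drop = FALSE]
    max_dist[b] <- max(sse_ratio_stat(Yp, Qn, Qa, warn = FALSE))
  }

  p_adj <- vapply(s_obs, function(s) (1 + sum(max_dist >= s)) / (1 + B),
                  numeric(1))
  critical <- perm_critical(max_dist, alpha)
  significant <- p_adj < alpha
  structure(list(
    table = tibble::tibble(patch = patch_ids(rownames(Y), nrow(Y)),
                           s_p = s_obs, p_adj = p_adj,
                           significant = significant),
    max_dist = max_dist, critical = critical, alpha = alpha,
    n_perm = B, seed = seed, scheme = scheme, contrast = contrast,
    exhaustive = exhaustive, group_col = group_col,
    n_subjects = n), class = "perm_result")
}

# largest order statistic m_(B-K) such that s > m_(B-K)  <=>  p_adj < alpha,
# with p_adj = (1 + #{m >= s}) / (1 + B)
perm_critical <- function(max_dist, alpha = 0.05) {
  B <- length(max_dist)
  K <- max(0L, ceiling(alpha * (1 + B)) - 1L)  # allowed exceedances
  if (K >= B) return(-Inf)
  sort(max_dist, partial = B - K)[B - K]
}

# all n! permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    left <- if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < n) sub[, pos:(n - 1L), drop = FALSE] else NULL
    out[r + seq_len(nrow(sub)), ] <- cbind(left, n, right)
    r <- r + nrow(sub)
  }
  out
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> contrast %s (%s), %d subjects, %d patches\n",
              x$contrast, x$scheme, x$n_subjects, nrow(x$table)))
  cat(sprintf("  %d permutations%s; critical s (alpha = %.2f) = %.4f\n",
              x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
              x$alpha, x$critical))
  cat(sprintf("  min adjusted p = %.4g; %d significant patch(es)\n",
              min(x$table$p_adj), sum(x$table$significant)))
  invisible(x)
}

#' Per-patch permutation results
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return Tibble with patch, s_p, p_adj, significant.
#' @method tidy perm_result
#' @export
tidy.perm_result <- function(x, ...) x$table

#' One-row summary of a permutation run
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return Tibble with contrast, scheme, n_subjects, n_patches, n_perm,
#'   critical value, minimum adjusted p and significant-patch count.
#' @method glance perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, scheme = x$scheme,
                 n_subjects = x$n_subjects, n_patches = nrow(x$table),
                 n_perm = x$n_perm, exhaustive = x$exhaustive,
                 critical = x$critical, min_p_adj = min(x$table$p_adj),
                 n_significant = sum(x$table$significant))
}

#' Plot the max-statistic permutation distribution
#'
#' Histogram of the permutation maxima with the critical value (dashed)
#' and the observed patch statistics (rug and points).
#'
#' @param object A `perm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_result
#' @export
autoplot.perm_result <- function(object, ...) {
  dist_df <- tibble::tibble(max_s = object$max_dist)
  obs <- object$table
  ggplot2::ggplot(dist_df, ggplot2::aes(x = .data$max_s)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$critical, linetype = "dashed") +
    ggplot2::geom_rug(data = obs,
                      ggplot2::aes(x = .data$s_p, colour = .data$significant),
                      sides = "b", linewidth = 1) +
    ggplot2::labs(x = "max-statistic (permutation)", y = "count",
                  title = sprintf("Max-statistic distribution: %s (%s)",
                                  object$contrast, object$scheme),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Percent atrophy of a patch in non-responders
#'
#' Reports 100 * (1 - mean(NR expansion) / mean(comparison-group
#' expansion)) for one patch: the relative patch-level area deficit of
#' non-responders against the contrast's comparison group (responders, or
#' everyone else).
#'
#' @param Y Feature matrix, patches x subjects.
#' @param cov Covariate table.
#' @param patch 0-based patch label.
#' @param contrast `"NR_vs_R"` or `"NR_vs_HCandR"`.
#' @param group_col Response-label column.
#' @return Percent atrophy (positive = NR smaller).
#' @export
percent_atrophy <- function(Y, cov, patch, contrast = "NR_vs_R",
                            group_col = "group") {
  cov <- validate_covariates(cov, group_col)
  keep <- contrast_subjects(cov, contrast, group_col)
  sub <- cov[keep, , drop = FALSE]
  Y <- Y[, as.character(sub$id), drop = FALSE]
  row <- match(paste0("patch_", patch), rownames(Y))
  if (is.na(row)) row <- patch + 1L
  y <- Y[row, ]
  is_nr <- as.character(sub[[group_col]]) == "NR"
  100 * (1 - mean(y[is_nr]) / mean(y[!is_nr]))
}

#' Table-style contrast report across structures and timepoints
#'
#' Runs the max-statistic permutation test for every structure x contrast
#' x timepoint combination and reports the minimum adjusted patch p-value
#' of each, with a significance marker at `alpha` — the grid summary the
#' shape analysis is read from.
#'
#' @param features Named list of feature matrices, one per structure.
#' @param cov Covariate table; each timepoint names a group column.
#' @param contrasts Character vector of contrasts to run.
#' @param timepoints Named character vector mapping timepoint name ->
#'   group column (default `c(acute = "group")`).
#' @param n_perm,seed,scheme,alpha Passed to [max_stat_permutation()].
#' @return Tibble (structure, contrast, timepoint, min_p_adj, best_patch,
#'   n_significant, significant).
#' @export
report_contrasts <- function(features, cov,
                             contrasts = c("NR_vs_R", "NR_vs_HCandR"),
                             timepoints = c(acute = "group"),
                             n_perm = 10000L, seed = 1L,
                             scheme = "shuffle_features", alpha = 0.05) {
  stopifnot(is.list(features), !is.null(names(features)))
  rows <- list()
  i <- 0L
  for (tp in names(timepoints)) {
    gcol <- timepoints[[tp]]
    if (!gcol %in% names(cov)) {
      warning("covariate table has no column '", gcol, "'; timepoint '",
              tp, "' skipped", call. = FALSE)
      next
    }
    for (ct in contrasts) for (st in names(features)) {
      Y <- features[[st]]
      if (is.null(Y)) {
        warning("structure '", st, "' missing; skipped", call. = FALSE)
        next
      }
      i <- i + 1L
      pr <- max_stat_permutation(Y, cov, ct, n_perm = n_perm,
                                 seed = seed + i, scheme = scheme,
                                 alpha = alpha, group_col = gcol)
      best <- which.min(pr$table$p_adj)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        structure = st, contrast = ct, timepoint = tp,
        min_p_adj = pr$table$p_adj[best],
        best_patch = pr$table$patch[best],
        n_significant = sum(pr$table$significant),
        significant = pr$table$significant[best])
    }
  }
  dplyr::bind_rows(rows)
}
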