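#' Validate a covariate table
#'
#' The covariate table is a data frame with one row per subject and
#' columns `id`, `age` (years), `sex` (0/1, female = 1), `icv` (mm^3) and
#' `group` in {"HC", "R", "NR"} (healthy comparison, responder,
#' non-responder). Additional group columns (e.g. `group_long` for a
#' second response timepoint) use the same vocabulary.
#'
#' @param cov Data frame of covariates.
#' @param group_col Name of the group column to check (default "group").
#' @return The table as a tibble, invisibly validated.
#' @export
validate_covariates <- function(cov, group_col = "group") {
  cov <- tibble::as_tibble(cov)
  need <- c("id", "age", "sex", "icv", group_col)
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stop("covariate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(cov[need])) stop("covariate table contains missing values",
                             call. = FALSE)
  if (anyDuplicated(cov$id)) stop("duplicate subject ids", call. = FALSE)
  bad <- setdiff(unique(as.character(cov[[group_col]])), c("HC", "R", "NR"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected HC, R, NR)", call. = FALSE)
  if (!all(cov$sex %in% c(0, 1)))
    stop("`sex` must be coded 0/1 (female = 1)", call. = FALSE)
  cov
}

#' Read / write a covariate table CSV
#' @param path CSV with header id,age,sex,icv,group[,group_long].
#' @return Tibble (read) or `path` (write).
#' @export
read_covariates <- function(path) {
  validate_covariates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_covariates
#' @param cov Covariate table.
#' @export
write_covariates <- function(cov, path) {
  utils::write.csv(cov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

contrast_names <- c("NR_vs_R", "NR_vs_HCandR")

# subjects entering a contrast, as a logical index into cov rows
contrast_subjects <- function(cov, contrast, group_col = "group") {
  contrast <- match.arg(contrast, contrast_names)
  g <- as.character(cov[[group_col]])
  if (contrast == "NR_vs_R") g %in% c("R", "NR") else rep(TRUE, length(g))
}

#' Design matrix for a response contrast
#'
#' Applies the contrast's subject-selection rule (`NR_vs_R` keeps only
#' responders and non-responders; `NR_vs_HCandR` keeps everyone) and
#' builds the columns (intercept, age, sex, ICV[, response]) in that
#' order, unstandardized. The response indicator is 1 for non-responders,
#' 0 otherwise.
#'
#' @param cov Covariate table (see [validate_covariates()]).
#' @param contrast `"NR_vs_R"` or `"NR_vs_HCandR"`.
#' @param with_response Include the response column (the alternative
#'   model); `FALSE` gives the nested null design.
#' @param group_col Group column holding the response labels for the
#'   timepoint being tested.
#' @return Numeric design matrix with attribute `subjects` (ids of the
#'   retained rows, in order).
#' @export
build_design <- function(cov, contrast = "NR_vs_R", with_response = TRUE,
                         group_col = "group") {
  cov <- validate_covariates(cov, group_col)
  keep <- contrast_subjects(cov, contrast, group_col)
  sub <- cov[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, age = sub$age, sex = sub$sex, icv = sub$icv)
  if (with_response)
    X <- cbind(X, response = as.numeric(as.character(sub[[group_col]]) == "NR"))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_col <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]][1L]
    stop("design matrix is rank deficient: column '", drop_col,
         "' is collinear in the selected subjects", call. = FALSE)
  }
  attr(X, "subjects") <- as.character(sub$id)
  X
}

#' Patch-wise ordinary least squares
#'
#' Fits every patch (row of Y) against the same design by OLS and records
#' the coefficients and residual sum of squares per patch.
#'
#' @param Y Feature matrix, patches x subjects; columns must match the
#'   design's subjects (matched by the design's `subjects` attribute when
#'   present).
#' @param X Design matrix from [build_design()].
#' @return Object of class `patch_glm`: `coefficients` (terms x patches),
#'   `sse` (per patch), `df_residual`, `fitted`, `residuals`.
#' @export
fit_glm <- function(Y, X) {
  Y <- align_features(Y, X)
  n <- ncol(Y)
  if (nrow(X) != n)
    stop("subjects in Y (", n, ") do not match design rows (", nrow(X), ")",
         call. = FALSE)
  if (n < ncol(X)) stop("fewer subjects than design columns", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  B <- qr.coef(qr_x, t(Y))                 # terms x patches
  fitted <- t(X %*% B)
  res <- Y - fitted
  structure(list(coefficients = B, sse = rowSums(res^2),
                 df_residual = n - ncol(X), fitted = fitted,
                 residuals = res, design = X,
                 patches = rownames(Y)),
            class = "patch_glm")
}

align_features <- function(Y, X) {
  subj <- attr(X, "subjects")
  if (!is.null(subj) && !is.null(colnames(Y))) {
    miss <- setdiff(subj, colnames(Y))
    if (length(miss))
      stop("feature matrix lacks subject(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    Y <- Y[, subj, drop = FALSE]
  }
  Y
}

#' @export
print.patch_glm <- function(x, ...) {
  cat(sprintf("<patch_glm> %d patches, %d subjects, %d terms\n",
              length(x$sse), ncol(x$residuals), nrow(x$coefficients)))
  invisible(x)
}

#' Tidy patch-wise GLM coefficients
#' @param x A `patch_glm`.
#' @param ... Unused.
#' @return Tibble with patch, term, estimate.
#' @method tidy patch_glm
#' @export
tidy.patch_glm <- function(x, ...) {
  B <- x$coefficients
  tibble::tibble(
    patch = rep(patch_ids(x$patches, ncol(B)), each = nrow(B)),
    term = rep(rownames(B), times = ncol(B)),
    estimate = as.numeric(B))
}

#' Per-patch fit summaries
#' @param x A `patch_glm`.
#' @param ... Unused.
#' @return Tibble with patch, sse, df_residual, sigma.
#' @method glance patch_glm
#' @export
glance.patch_glm <- function(x, ...) {
  tibble::tibble(patch = patch_ids(x$patches, length(x$sse)),
                 sse = x$sse, df_residual = x$df_residual,
                 sigma = sqrt(x$sse / x$df_residual))
}

patch_ids <- function(patches, k) {
  if (is.null(patches)) return(seq_len(k) - 1L)
  as.integer(sub("^patch_", "", patches))
}

#' Nested-model SSE-ratio statistic per patch
#'
#' For each patch p, `s_p = SSE_null(p) / SSE_alt(p)` where the null model
#' regresses the patch feature on (intercept, age, sex, ICV) and the
#' alternative adds the response indicator. s_p >= 1 always; it is a
#' monotone transform of the partial F statistic for the response column:
#' s_p = 1 + F / (n - p_alt).
#'
#' @param Y Feature matrix, patches x subjects.
#' @param cov Covariate table.
#' @param contrast `"NR_vs_R"` or `"NR_vs_HCandR"`.
#' @param group_col Response-label column for the timepoint tested.
#' @return Tibble with columns `patch` (0-based) and `s_p`. Patches with a
#'   perfect alternative fit get `s_p = Inf` with a warning.
#' @export
sse_ratio <- function(Y, cov, contrast = "NR_vs_R", group_col = "group") {
  X_alt <- build_design(cov, contrast, TRUE, group_col)
  X_null <- build_design(cov, contrast, FALSE, group_col)
  Y <- align_features(Y, X_alt)
  s <- sse_ratio_stat(Y, proj_residual(X_null), proj_residual(X_alt))
  tibble::tibble(patch = patch_ids(rownames(Y), nrow(Y)), s_p = s)
}

# residual-forming projection I - X (X'X)^-1 X', assembled from the thin QR
# of X (stable even with mm^3-scale covariate columns)
proj_residual <- function(X) {
  Q1 <- qr.Q(qr(X))
  diag(nrow(X)) - tcrossprod(Q1)
}

# s_p vector given residual projectors; Inf (with warning) on perfect fits
# (an alternative-model SSE at round-off level relative to the feature scale)
sse_ratio_stat <- function(Y, Q_null, Q_alt, warn = TRUE) {
  sse_n <- rowSums((Y %*% Q_null) * Y)
  sse_a <- rowSums((Y %*% Q_alt) * Y)
  perfect <- sse_a <= 1e-12 * pmax(rowSums(Y * Y), .Machine$double.xmin)
  s <- ifelse(perfect, Inf, sse_n / sse_a)
  if (warn && any(!is.finite(s)))
    warning("perfect alternative-model fit in ", sum(!is.finite(s)),
            " patch(es); s_p reported as Inf", call. = FALSE)
  unname(pmax(s, 1))  # guard round-off below 1 for nested models
}
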