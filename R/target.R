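#' Fit the cohort (target) model
#'
#' Fits, per CpG of the signature, the cohort beta values against the
#' covariate design (intercept plus the covariate columns of the sheet, in
#' sheet order).  With two or more bead chips a linear mixed model with a
#' random chip intercept is fitted by REML; otherwise ordinary least
#' squares.  The residual sum of squares summed over signature CpGs and
#' samples (SSe) enters the variance decomposition; under the mixed model
#' it is the sum of squared conditional residuals (observed minus fixed +
#' chip predictions).
#'
#' Covariates are used exactly as supplied -- centering (e.g. of age) is
#' the caller's responsibility.
#'
#' @param cohort a [beta_matrix()] of whole-blood samples.
#' @param covariates a cohort-schema `sample_sheet`.
#' @param signature character vector of CpG IDs (typically from
#'   [select_top_cpgs()]); order defines the row order of the fit.
#' @return An object of class `target_fit` with `cpg_ids`, `B1`
#'   (m x d1, intercept first), `Z` (n1 x d1 design), `SSe`,
#'   `per_cpg_resid_var`, `sample_ids`, `chip_ids`.
#' @export
fit_target_model <- function(cohort, covariates, signature = rownames(cohort)) {
  stopifnot(inherits(cohort, "beta_matrix"),
            inherits(covariates, "sample_sheet"))
  if (!identical(attr(covariates, "schema"), "cohort"))
    stop("fit_target_model needs a cohort-schema sample sheet", call. = FALSE)
  absent <- setdiff(signature, rownames(cohort))
  if (length(absent) > 0)
    stop("signature CpG(s) absent from cohort: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ...", call. = FALSE)
  missing_samples <- setdiff(covariates$sample_id, colnames(cohort))
  if (length(missing_samples) > 0)
    stop("sample(s) in sheet absent from beta matrix: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  Y <- unclass(cohort)[signature, covariates$sample_id, drop = FALSE]
  if (anyNA(Y))
    stop("cohort beta matrix contains missing values in the signature; ",
         "filter with complete_cpgs() first", call. = FALSE)

  covar_cols <- attr(covariates, "covariates")
  Z <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[, covar_cols, drop = FALSE]))
  rownames(Z) <- covariates$sample_id
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dep <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("rank-deficient cohort design; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }

  chips <- covariates$chip_id
  use_mixed <- length(unique(chips[!is.na(chips)])) >= 2
  if (use_mixed) {
    fit <- fit_target_mixed(Y, Z, chips)
  } else {
    fit <- fit_target_ols(Y, Z)
  }
  structure(list(
    cpg_ids = signature,
    B1 = fit$B1,
    Z = Z,
    SSe = sum(fit$rss),
    per_cpg_resid_var = fit$resid_var,
    sample_ids = covariates$sample_id,
    chip_ids = chips,
    mixed = use_mixed,
    Y = Y
  ), class = "target_fit")
}

fit_target_ols <- function(Y, Z) {
  M <- solve(crossprod(Z))
  B1 <- Y %*% Z %*% M
  dimnames(B1) <- list(rownames(Y), colnames(Z))
  resid <- Y - tcrossprod(B1, Z)
  rss <- rowSums(resid^2)
  dfr <- ncol(Y) - ncol(Z)
  list(B1 = B1, rss = rss,
       resid_var = if (dfr > 0) rss / dfr else rep(0, nrow(Y)))
}

fit_target_mixed <- function(Y, Z, chips) {
  chips <- factor(ifelse(is.na(chips), "<none>", chips))
  m <- nrow(Y)
  B1 <- matrix(NA_real_, m, ncol(Z), dimnames = list(rownames(Y), colnames(Z)))
  rss <- numeric(m)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  ols <- fit_target_ols(Y, Z)
  for (j in seq_len(m)) {
    y <- Y[j, ]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 0 + Z + (1 | chips), REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit)) {
      B1[j, ] <- ols$B1[j, ]
      rss[j] <- ols$rss[j]
      next
    }
    B1[j, ] <- lme4::fixef(fit)
    rss[j] <- sum(stats::residuals(fit)^2)  # conditional residuals
  }
  dfr <- ncol(Y) - ncol(Z)
  list(B1 = B1, rss = rss,
       resid_var = if (dfr > 0) rss / dfr else rep(0, m))
}

#' @export
print.target_fit <- function(x, ...) {
  cat("Target fit:", length(x$cpg_ids), "CpGs,",
      length(x$sample_ids), "samples, design columns:",
      paste(colnames(x$Z), collapse = ", "), "\n")
  cat("  SSe =", format(x$SSe), "\n")
  invisible(x)
}
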