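#' Naive least-squares standard errors
#'
#' Classical OLS standard errors for the linking regression of the cohort
#' coefficients on \eqn{(1_m, B_0)}, treating both coefficient matrices as
#' fixed (i.e. ignoring that they are themselves estimates).  The residual
#' variance is taken per covariate column from the corresponding column of
#' the residual matrix U.
#'
#' @param ref a `reference_fit` (signature CpGs).
#' @param target the matching `target_fit`.
#' @param projection the `projection_result`.
#' @return (d0+1) x d1 matrix of standard errors in percentage points.
#' @export
naive_se <- function(ref, target, projection) {
  Bt <- cbind(`(Intercept)` = 1, ref$B0)
  m <- nrow(Bt)
  p <- ncol(Bt)
  M <- solve(crossprod(Bt))
  dfr <- m - p
  # saturated projection (m == d0 + 1): residuals are identically zero
  sigma2 <- if (dfr > 0) colSums(projection$U^2) / dfr
            else rep(0, ncol(projection$U))
  se <- sqrt(outer(diag(M), sigma2)) * 100
  dimnames(se) <- dimnames(projection$coef)
  se
}

#' Bootstrap inference for mixture-shift coefficients
#'
#' Single bootstrap: cohort subjects are resampled with replacement, the
#' cohort coefficients are refitted (by OLS, for speed and stability of the
#' resampled design) and re-projected; SE1 is the standard deviation of the
#' replicate estimates.  Double bootstrap: additionally, each replicate
#' draws a perturbed reference matrix B0* from the normal sampling
#' distribution implied by the per-CpG coefficient covariances (a
#' parametric bootstrap of the purified panel) before re-projecting; SE2 is
#' the replicate standard deviation and `Bias2`, the mean replicate
#' estimate minus the point estimate, measures bias due to measurement
#' error in B0.  The bias-corrected estimate is `est - Bias2`.
#'
#' Replicates whose resampled design loses full rank (e.g. a covariate
#' level vanishing) are dropped with a message; more than 20% drops is an
#' error.
#'
#' @param ref `reference_fit` on the signature CpGs.
#' @param target matching `target_fit` (carries the cohort data and design).
#' @param mode `"double"` (default; computes SE1 and SE2) or `"single"`.
#' @param n_boot number of bootstrap replicates (default 250; large
#'   simulation studies typically use 50).
#' @param seed integer seed for reproducibility (optional).
#' @return An object of class `inference_result`: `est`, `se0`, `se1`,
#'   `se2`, `bias2`, `est_corrected` (all (d0+1) x d1, percentage points),
#'   replicate arrays, `n_boot`, `n_dropped`, `mode`, `seed`.  Run
#'   [wald_inference()] to add z-scores, p-values and confidence intervals.
#' @export
bootstrap_inference <- function(ref, target, mode = c("double", "single"),
                                n_boot = 250, seed = NULL) {
  mode <- match.arg(mode)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  projection <- project_onto_reference(ref, target)
  est <- projection$coef * 100
  Bt <- cbind(`(Intercept)` = 1, ref$B0)
  Y <- target$Y
  Z <- target$Z
  n1 <- nrow(Z)
  d <- ncol(projection$coef)
  p <- nrow(projection$coef)

  Rarr <- if (mode == "double") chol_cov_array(ref$coef_cov) else NULL
  single_reps <- array(NA_real_, c(p, d, n_boot))
  double_reps <- if (mode == "double") array(NA_real_, c(p, d, n_boot))
  BtB <- crossprod(Bt)
  dropped <- 0L
  for (t in seq_len(n_boot)) {
    idx <- sample.int(n1, n1, replace = TRUE)
    Zb <- Z[idx, , drop = FALSE]
    ZtZ <- crossprod(Zb)
    ok <- tryCatch({solve(ZtZ); TRUE}, error = function(e) FALSE)
    if (!ok || qr(Zb)$rank < ncol(Zb)) {
      dropped <- dropped + 1L
      next
    }
    B1b <- Y[, idx, drop = FALSE] %*% Zb %*% solve(ZtZ)
    single_reps[, , t] <- solve(BtB, crossprod(Bt, B1b))
    if (mode == "double") {
      B0s <- ref$B0 + perturb_rows(Rarr)
      Bts <- cbind(1, B0s)
      double_reps[, , t] <- solve(crossprod(Bts), crossprod(Bts, B1b))
    }
  }
  if (dropped > 0.2 * n_boot)
    stop("bootstrap failed: ", dropped, "/", n_boot,
         " replicates had a collapsed design", call. = FALSE)
  if (dropped > 0)
    message(dropped, " bootstrap replicate(s) dropped (collapsed design)")

  sd_slice <- function(reps) {
    out <- apply(reps, c(1, 2), stats::sd, na.rm = TRUE) * 100
    dimnames(out) <- dimnames(est)
    out
  }
  mean_slice <- function(reps) {
    out <- apply(reps, c(1, 2), mean, na.rm = TRUE) * 100
    dimnames(out) <- dimnames(est)
    out
  }
  se1 <- sd_slice(single_reps)
  se2 <- if (mode == "double") sd_slice(double_reps) else NULL
  bias2 <- if (mode == "double") mean_slice(double_reps) - est else est * 0
  res <- structure(list(
    est = est,
    se0 = naive_se(ref, target, projection),
    se1 = se1,
    se2 = se2,
    bias2 = bias2,
    est_corrected = est - bias2,
    replicates = (if (mode == "double") double_reps else single_reps) * 100,
    single_replicates = single_reps * 100,
    n_boot = n_boot,
    n_dropped = dropped,
    mode = mode,
    seed = seed,
    projection = projection,
    cell_types = ref$cell_types
  ), class = "inference_result")
  wald_inference(res)
}

# upper-triangular Cholesky factors of the per-CpG coefficient covariances,
# stacked as an m x d0 x d0 array (rows of zero covariance give zeros)
chol_cov_array <- function(coef_cov) {
  m <- dim(coef_cov)[1]
  d0 <- dim(coef_cov)[2]
  R <- array(0, dim(coef_cov))
  for (j in seq_len(m)) {
    S <- coef_cov[j, , ]
    if (all(abs(S) < 1e-300)) next
    R[j, , ] <- chol(S + diag(1e-12 * max(diag(S)), d0))
  }
  R
}

# one draw of the m x d0 perturbation matrix E with rows z_j' R_j
perturb_rows <- function(Rarr) {
  m <- dim(Rarr)[1]
  d0 <- dim(Rarr)[2]
  Zr <- matrix(stats::rnorm(m * d0), m, d0)
  E <- matrix(0, m, d0)
  for (k in seq_len(d0)) E[, k] <- rowSums(Zr * Rarr[, , k])
  E
}

#' Wald tests and confidence intervals
#'
#' z-scores use the uncorrected estimate over the double-bootstrap standard
#' error (SE1 in single mode); p-values are two-sided normal.  95%
#' confidence intervals are `est_corrected +/- z_{0.975} * SE`.
#'
#' @param result an `inference_result`.
#' @param level confidence level (default 0.95).
#' @return The result with `z_scores`, `p_values`, `ci_lower`, `ci_upper`.
#' @export
wald_inference <- function(result, level = 0.95) {
  stopifnot(inherits(result, "inference_result"))
  se <- if (!is.null(result$se2)) result$se2 else result$se1
  z <- result$est / se
  zero_se <- !is.na(se) & se == 0
  z[zero_se & result$est == 0] <- 0
  if (any(zero_se & result$est != 0)) {
    warning("zero bootstrap SE with nonzero estimate; p-value set to 0")
    z[zero_se & result$est != 0] <- Inf * sign(result$est[zero_se &
                                                          result$est != 0])
  }
  result$z_scores <- z
  result$p_values <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  result$ci_lower <- result$est_corrected - q * se
  result$ci_upper <- result$est_corrected + q * se
  result
}

#' Linear transformation of mixture-shift estimates
#'
#' Applies a linear combination of covariate columns to the estimates --
#' e.g. adding the intercept column to a group indicator column to recover
#' the group-specific cell composition -- propagating uncertainty through
#' the stored bootstrap replicates and applying the same bias correction.
#'
#' @param result an `inference_result` with stored replicates.
#' @param L d1 x q matrix of column combinations (column names become the
#'   names of the transformed quantities).
#' @return An `inference_result` for the transformed quantities (naive SE0
#'   is not defined for combinations and is reported as NA).
#' @export
transform_gamma <- function(result, L) {
  stopifnot(inherits(result, "inference_result"))
  if (is.null(result$replicates))
    stop("no stored bootstrap replicates; run bootstrap_inference() first",
         call. = FALSE)
  L <- as.matrix(L)
  d1 <- ncol(result$est)
  if (nrow(L) != d1)
    stop("L must have ", d1, " rows (one per covariate column)",
         call. = FALSE)
  if (is.null(colnames(L)))
    colnames(L) <- paste0("L", seq_len(ncol(L)))
  est <- result$est %*% L
  n_boot <- dim(result$replicates)[3]
  tr_reps <- array(NA_real_, c(nrow(est), ncol(L), n_boot))
  tr_single <- tr_reps
  for (t in seq_len(n_boot)) {
    tr_reps[, , t] <- result$replicates[, , t] %*% L
    tr_single[, , t] <- result$single_replicates[, , t] %*% L
  }
  sdns <- function(reps) {
    out <- apply(reps, c(1, 2), stats::sd, na.rm = TRUE)
    dimnames(out) <- dimnames(est)
    out
  }
  bias2 <- result$bias2 %*% L
  se1 <- sdns(tr_single)
  se2 <- if (result$mode == "double") sdns(tr_reps) else NULL
  res <- structure(list(
    est = est,
    se0 = est * NA,
    se1 = se1,
    se2 = se2,
    bias2 = bias2,
    est_corrected = est - bias2,
    replicates = tr_reps,
    single_replicates = tr_single,
    n_boot = result$n_boot,
    n_dropped = result$n_dropped,
    mode = result$mode,
    seed = result$seed,
    cell_types = result$cell_types
  ), class = "inference_result")
  wald_inference(res)
}

#' Sensitivity analysis for non-cell-mediated differences
#'
#' If the case/control difference in non-cell-mediated methylation,
#' \eqn{\delta}, has a nonzero projection onto the reference column space
#' (\eqn{\delta = B_0 \alpha}), the mixture-shift estimates carry an
#' additive bias of \eqn{\alpha}.  This routine computes that worst-case
#' bias for a candidate \eqn{\delta}.
#'
#' @param ref a `reference_fit` on the signature CpGs.
#' @param delta numeric m-vector (beta-value difference per CpG), aligned
#'   with the signature; names, when present, are checked.
#' @return Object of class `sensitivity_result` with `alpha` (d0 vector,
#'   percentage points).
#' @export
sensitivity_alpha <- function(ref, delta) {
  stopifnot(inherits(ref, "reference_fit"))
  if (length(delta) != length(ref$cpg_ids))
    stop("delta has length ", length(delta), " but the signature has ",
         length(ref$cpg_ids), " CpGs", call. = FALSE)
  if (!is.null(names(delta)) && !identical(names(delta), ref$cpg_ids))
    stop("delta names do not match the signature CpG order", call. = FALSE)
  alpha <- drop(solve(crossprod(ref$B0), crossprod(ref$B0, delta))) * 100
  names(alpha) <- ref$cell_types
  structure(list(alpha = alpha), class = "sensitivity_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("Mixture-shift inference (", x$mode, " bootstrap, n_boot = ",
      x$n_boot, ")\n", sep = "")
  for (cv in colnames(x$est)) {
    cat("--", cv, "(percentage points) --\n")
    tab <- cbind(Est = x$est[, cv], Bias2 = x$bias2[, cv],
                 SE0 = x$se0[, cv], SE1 = x$se1[, cv],
                 SE2 = if (!is.null(x$se2)) x$se2[, cv] else NA,
                 `P-value` = x$p_values[, cv])
    print(round(tab, 4))
  }
  invisible(x)
}
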