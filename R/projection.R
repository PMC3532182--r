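#' Project cohort coefficients onto the reference cell-type space
#'
#' Solves, column by column, the least-squares linking regression of the
#' cohort coefficient matrix B1 on the augmented reference matrix
#' \eqn{\tilde B_0 = (1_m, B_0)}.  The first solved row is the intercept
#' row \eqn{\gamma_0}; the remaining d0 rows form the mixture-shift matrix
#' \eqn{\Gamma}, whose entry (l, k) is the change in the population-average
#' proportion of cell type l per unit of covariate k (fraction units here;
#' multiply by 100 for percentage points).  \eqn{\Gamma} is deliberately
#' left unconstrained at the population level -- non-negativity applies
#' only to per-sample deconvolution ([deconvolve_sample()]).
#'
#' @param ref a `reference_fit` restricted to the signature CpGs.
#' @param target a `target_fit` on the same CpGs in the same order.
#' @return An object of class `projection_result` with `gamma0` (1 x d1),
#'   `Gamma` (d0 x d1), `coef` (their (d0+1) x d1 stack), and the residual
#'   matrix `U` (m x d1, orthogonal to the column space of
#'   \eqn{\tilde B_0}).
#' @export
project_onto_reference <- function(ref, target) {
  stopifnot(inherits(ref, "reference_fit"), inherits(target, "target_fit"))
  if (!identical(ref$cpg_ids, target$cpg_ids))
    stop("reference and target CpG sets are not aligned; subset and order ",
         "them identically (see subset_reference())", call. = FALSE)
  Bt <- cbind(`(Intercept)` = 1, ref$B0)
  qb <- qr(Bt)
  if (qb$rank < ncol(Bt)) {
    dep <- colnames(Bt)[qb$pivot[(qb$rank + 1):ncol(Bt)]]
    stop("reference design (1, B0) is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coef <- solve(crossprod(Bt), crossprod(Bt, target$B1))
  U <- target$B1 - Bt %*% coef
  structure(list(
    gamma0 = coef[1, , drop = FALSE],
    Gamma = coef[-1, , drop = FALSE],
    coef = coef,
    U = U,
    B0 = ref$B0,
    cell_types = ref$cell_types,
    cpg_ids = ref$cpg_ids
  ), class = "projection_result")
}

#' Variance decomposition and coefficients of determination
#'
#' Splits the total variation SSo of the cohort methylation values into
#' `SSo = SSe + SSv + SSu`: residual noise (SSe, from the target fit),
#' variation explained by mixtures of the reference profiles (SSv), and
#' systematic variation unexplained by such mixtures (SSu).  Two partial
#' coefficients of determination follow: `R2_10 = SSv/SSo`, the share of
#' total variation explained by cell mixture, and `R2_11 = SSv/(SSo-SSe)`,
#' the share of systematic variation so explained.  SSo is assembled from
#' the decomposition (additivity is exact by construction); `R2_11` is
#' flagged undefined when `SSo - SSe < 1e-3 * SSo`, where it is poorly
#' determined.
#'
#' @param projection a `projection_result`.
#' @param target the `target_fit` used to compute it.
#' @return The `projection_result` with `SSo`, `SSe`, `SSv`, `SSu`,
#'   `R2_10`, `R2_11`, `R2_11_defined` added.
#' @export
decompose_variance <- function(projection, target) {
  stopifnot(inherits(projection, "projection_result"),
            inherits(target, "target_fit"))
  Z <- target$Z
  Zc <- sweep(Z, 2, colMeans(Z))
  # SSv = sum_i || B0 Gamma (z_i - zbar) ||^2
  SSv <- sum((tcrossprod(projection$B0 %*% projection$Gamma, Zc))^2)
  m <- length(projection$cpg_ids)
  SSu <- sum((tcrossprod(projection$U, Zc))^2) +
    m * sum((Zc %*% t(projection$gamma0))^2)
  SSe <- target$SSe
  SSo <- SSe + SSv + SSu
  projection$SSe <- SSe
  projection$SSv <- SSv
  projection$SSu <- SSu
  projection$SSo <- SSo
  projection$R2_10 <- if (SSo > 0) SSv / SSo else NA_real_
  projection$R2_11_defined <- (SSo - SSe) >= 1e-3 * SSo
  projection$R2_11 <- if (isTRUE(projection$R2_11_defined))
    SSv / (SSo - SSe) else NA_real_
  projection
}

#' @export
print.projection_result <- function(x, ...) {
  cat("Projection of cohort coefficients onto (1, B0)\n")
  cat("Gamma (percentage points):\n")
  print(round(100 * x$Gamma, 2))
  if (!is.null(x$SSo)) {
    cat(sprintf("SSo = %.4g = SSe %.4g + SSv %.4g + SSu %.4g\n",
                x$SSo, x$SSe, x$SSv, x$SSu))
    cat(sprintf("R2_10 = %.3f   R2_11 = %s\n", x$R2_10,
                if (isTRUE(x$R2_11_defined)) sprintf("%.3f", x$R2_11)
                else "undefined (SSo ~ SSe)"))
  }
  invisible(x)
}
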