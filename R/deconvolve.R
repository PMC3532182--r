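#' Non-negative least squares with free columns
#'
#' Lawson-Hanson-style active-set solver for
#' \eqn{\min_b \|y - X b\|^2} subject to \eqn{b_j \ge 0} for the
#' constrained columns, with the columns listed in `free` unconstrained.
#' Deterministic; terminates at an exact KKT point (gradient components at
#' active zero constraints are non-positive within `tol`).
#'
#' @param X numeric matrix (m x p), full column rank.
#' @param y numeric m-vector.
#' @param free integer indices of unconstrained columns (default none).
#' @param tol KKT tolerance on the gradient (default 1e-9).
#' @return List with `coef`, `residual_norm`, `iterations`.
#' @export
nnls_free <- function(X, y, free = integer(), tol = 1e-9) {
  p <- ncol(X)
  m <- nrow(X)
  if (length(y) != m) stop("dimension mismatch between X and y",
                           call. = FALSE)
  constrained <- setdiff(seq_len(p), free)
  b <- numeric(p)
  inP <- rep(FALSE, p)
  inP[free] <- TRUE
  solve_P <- function(P) {
    qr.coef(qr(X[, P, drop = FALSE]), y)
  }
  # scale-aware tolerance for the optimality test
  gtol <- max(tol, tol * sum(abs(crossprod(X, y))))
  iter <- 0L
  max_iter <- 30L * p
  if (any(inP)) {
    s <- solve_P(which(inP))
    if (anyNA(s))
      stop("free columns of X are rank deficient", call. = FALSE)
    b[inP] <- s
  }
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("NNLS failed to converge; design condition number ",
           format(kappa(X)), call. = FALSE)
    w <- drop(crossprod(X, y - X %*% b))
    cand <- constrained[!inP[constrained]]
    if (length(cand) == 0 || max(w[cand]) <= gtol) break
    j <- cand[which.max(w[cand])]
    inP[j] <- TRUE
    repeat {
      P <- which(inP)
      s_full <- numeric(p)
      s <- solve_P(P)
      if (anyNA(s)) { # degenerate subset: back out the entering column
        inP[j] <- FALSE
        break
      }
      s_full[P] <- s
      neg <- intersect(P, constrained)
      neg <- neg[s_full[neg] < 0]
      if (length(neg) == 0) {
        b <- s_full
        break
      }
      alpha <- min(b[neg] / (b[neg] - s_full[neg]))
      b <- b + alpha * (s_full - b)
      drop_idx <- intersect(P, constrained)
      drop_idx <- drop_idx[b[drop_idx] <= tol]
      b[drop_idx] <- 0
      inP[drop_idx] <- FALSE
    }
  }
  list(coef = b, residual_norm = sqrt(sum((y - X %*% b)^2)),
       iterations = iter)
}

#' Deconvolve a single methylation profile
#'
#' Estimates the leukocyte composition of one sample by minimising
#' \eqn{\|y - \tilde B_0 (\gamma_0^*; \Gamma^*)\|^2} with the d0 cell-type
#' components constrained to be non-negative; the intercept (absorbing
#' non-cell signal) is left unconstrained.  The proportions are not
#' constrained to sum to one -- a sum close to 100% is itself evidence that
#' the profile is well explained by the reference cell types.
#'
#' @param ref a `reference_fit` on the signature CpGs.
#' @param y numeric vector of beta values aligned with (and optionally
#'   named by) the signature CpGs; no missing values.
#' @param normalize if `TRUE`, additionally report proportions rescaled to
#'   sum to one (off by default; the raw sum is diagnostic).
#' @return Object of class `sample_mixture`: `proportions` (named d0
#'   vector, fractions), `intercept`, `residual_norm`, `proportions_sum`,
#'   and `proportions_normalized` when requested.
#' @export
deconvolve_sample <- function(ref, y, normalize = FALSE) {
  stopifnot(inherits(ref, "reference_fit"))
  if (length(y) != length(ref$cpg_ids))
    stop("profile has length ", length(y), " but the signature has ",
         length(ref$cpg_ids), " CpGs", call. = FALSE)
  if (!is.null(names(y)) && !identical(names(y), ref$cpg_ids))
    stop("profile CpG names do not match the signature order", call. = FALSE)
  if (anyNA(y))
    stop("profile contains missing values; filter CpGs first", call. = FALSE)
  Bt <- cbind(`(Intercept)` = 1, ref$B0)
  sol <- nnls_free(Bt, as.numeric(y), free = 1L)
  props <- sol$coef[-1]
  names(props) <- ref$cell_types
  out <- list(proportions = props,
              intercept = sol$coef[1],
              residual_norm = sol$residual_norm,
              proportions_sum = sum(props))
  if (normalize)
    out$proportions_normalized <- if (sum(props) > 0) props / sum(props)
                                  else props
  structure(out, class = "sample_mixture")
}

#' Deconvolve every sample of a cohort
#'
#' @param ref a `reference_fit` on the signature CpGs.
#' @param cohort a [beta_matrix()] whose rows cover the signature.
#' @param normalize passed to [deconvolve_sample()].
#' @return Data frame with one row per sample: `sample_id`, one column per
#'   cell type (fractions), `sum`, `residual_norm`.  Samples that fail are
#'   omitted and listed in the `failures` attribute.
#' @export
deconvolve_cohort <- function(ref, cohort, normalize = FALSE) {
  stopifnot(inherits(cohort, "beta_matrix"))
  absent <- setdiff(ref$cpg_ids, rownames(cohort))
  if (length(absent) > 0)
    stop("signature CpG(s) absent from cohort: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  Y <- unclass(cohort)[ref$cpg_ids, , drop = FALSE]
  rows <- vector("list", ncol(Y))
  failures <- character()
  for (i in seq_len(ncol(Y))) {
    sid <- colnames(Y)[i]
    mix <- tryCatch(deconvolve_sample(ref, unname(Y[, i]),
                                      normalize = normalize),
                    error = function(e) e)
    if (inherits(mix, "error")) {
      failures <- c(failures, stats::setNames(conditionMessage(mix), sid))
      next
    }
    rows[[i]] <- data.frame(sample_id = sid,
                            as.list(mix$proportions),
                            sum = mix$proportions_sum,
                            residual_norm = mix$residual_norm,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character())
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' @export
print.sample_mixture <- function(x, ...) {
  cat("Estimated cell-type proportions (sum ",
      sprintf("%.1f%%", 100 * x$proportions_sum), "):\n", sep = "")
  print(round(100 * x$proportions, 2))
  cat("intercept", sprintf("%.4f", x$intercept),
      "| residual norm", sprintf("%.4f", x$residual_norm), "\n")
  invisible(x)
}
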