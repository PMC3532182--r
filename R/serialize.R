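#' Serialize a reference fit to JSON
#'
#' Matrices are stored row-major alongside their identifier vectors so the
#' file is self-describing and portable.
#'
#' @param fit a `reference_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fit <- function(fit, path) {
  stopifnot(inherits(fit, "reference_fit"))
  obj <- list(
    format = "leukodecon/reference_fit/1",
    cpg_ids = fit$cpg_ids,
    cell_types = fit$cell_types,
    B0 = as.vector(t(fit$B0)),
    coef_cov = as.vector(aperm(fit$coef_cov, c(3, 2, 1))),
    sigma2_chip = fit$sigma2_chip,
    sigma2_resid = fit$sigma2_resid,
    F_stats = fit$F_stats,
    df = fit$df,
    n0 = fit$n0,
    mixed = fit$mixed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a reference fit written by [write_reference_fit()]
#' @param path JSON path.
#' @return A `reference_fit`.
#' @export
read_reference_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "leukodecon/reference_fit/1"))
    stop("not a serialized reference fit: ", path, call. = FALSE)
  m <- length(obj$cpg_ids)
  d0 <- length(obj$cell_types)
  B0 <- matrix(obj$B0, m, d0, byrow = TRUE,
               dimnames = list(obj$cpg_ids, obj$cell_types))
  coef_cov <- aperm(array(obj$coef_cov, c(d0, d0, m)), c(3, 2, 1))
  dimnames(coef_cov) <- list(obj$cpg_ids, obj$cell_types, obj$cell_types)
  structure(list(
    cpg_ids = obj$cpg_ids, B0 = B0, coef_cov = coef_cov,
    sigma2_chip = obj$sigma2_chip, sigma2_resid = obj$sigma2_resid,
    F_stats = obj$F_stats, df = obj$df, cell_types = obj$cell_types,
    n0 = obj$n0, mixed = obj$mixed, n_fallback = NA_integer_,
    design = NULL
  ), class = "reference_fit")
}

#' Serialize a target fit to JSON
#' @param fit a `target_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_fit <- function(fit, path) {
  stopifnot(inherits(fit, "target_fit"))
  obj <- list(
    format = "leukodecon/target_fit/1",
    cpg_ids = fit$cpg_ids,
    design_columns = colnames(fit$Z),
    sample_ids = fit$sample_ids,
    B1 = as.vector(t(fit$B1)),
    Z = as.vector(t(fit$Z)),
    Y = as.vector(t(fit$Y)),
    SSe = fit$SSe,
    per_cpg_resid_var = fit$per_cpg_resid_var,
    chip_ids = fit$chip_ids,
    mixed = fit$mixed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a target fit written by [write_target_fit()]
#' @param path JSON path.
#' @return A `target_fit`.
#' @export
read_target_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "leukodecon/target_fit/1"))
    stop("not a serialized target fit: ", path, call. = FALSE)
  m <- length(obj$cpg_ids)
  d1 <- length(obj$design_columns)
  n1 <- length(obj$sample_ids)
  structure(list(
    cpg_ids = obj$cpg_ids,
    B1 = matrix(obj$B1, m, d1, byrow = TRUE,
                dimnames = list(obj$cpg_ids, obj$design_columns)),
    Z = matrix(obj$Z, n1, d1, byrow = TRUE,
               dimnames = list(obj$sample_ids, obj$design_columns)),
    SSe = obj$SSe,
    per_cpg_resid_var = obj$per_cpg_resid_var,
    sample_ids = obj$sample_ids,
    chip_ids = obj$chip_ids,
    mixed = obj$mixed,
    Y = matrix(obj$Y, m, n1, byrow = TRUE,
               dimnames = list(obj$cpg_ids, obj$sample_ids))
  ), class = "target_fit")
}
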