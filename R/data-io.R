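#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a numeric CpG x sample matrix of DNA methylation beta
#' values (fraction of methylated molecules at each CpG, in \[0,1\]).  Row
#' names are CpG identifiers, column names are sample identifiers; `NA`
#' marks a missing assay value.
#'
#' @param values numeric matrix, CpGs in rows, samples in columns.
#' @param cpg_ids,sample_ids optional identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @return An object of class `beta_matrix` (a validated numeric matrix).
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("beta_matrix requires CpG and sample identifiers", call. = FALSE)
  rownames(values) <- as.character(cpg_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

validate_beta_matrix <- function(values) {
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value outside [0,1] at CpG '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "' (value ",
         format(values[bad[1, , drop = FALSE]]), ")", call. = FALSE)
  }
  invisible(values)
}

#' Read a beta-value matrix from CSV/TSV
#'
#' The first column must hold CpG identifiers and the header row sample
#' identifiers.  Empty cells and the string `"NA"` are read as missing.
#' Non-numeric cells and values outside \[0,1\] are errors that name the
#' offending CpG and sample.
#'
#' @param path path to a delimited text file.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), comment.char = "",
                           quote = "\"")
  if (ncol(raw) < 2)
    stop("beta matrix file needs a CpG ID column plus >=1 sample column",
         call. = FALSE)
  cpg_ids <- raw[[1]]
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samples))
  for (j in seq_along(samples)) {
    cell <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0)
      stop("non-numeric beta value '", cell[bad[1]], "' at CpG '",
           cpg_ids[bad[1]], "', sample '", samples[j], "'", call. = FALSE)
    vals[, j] <- num
  }
  beta_matrix(vals, cpg_ids = cpg_ids, sample_ids = samples)
}

#' Read a panel or cohort sample sheet
#'
#' Panel sheets describe the purified-cell validation set: they require
#' `sample_id` and `cell_type` columns and may carry an optional `chip_id`
#' batch column plus fractional-membership columns named after cell types
#' (e.g. a Pan-T sample with `CD4T = 0.65, CD8T = 0.35`).  Cohort sheets
#' require `sample_id`, optionally `chip_id`, and treat every remaining
#' numeric column as a covariate.
#'
#' @param path CSV file path.
#' @param schema `"panel"` or `"cohort"`.
#' @param control_types cell-type labels (panel schema) to be modelled as
#'   extra design columns -- e.g. whole-blood array controls -- estimated
#'   during fitting but excluded from the reported reference profiles.
#' @param cell_types optional explicit cell-type vocabulary (panel schema);
#'   by default it is inferred from the pure labels and the fractional
#'   column names.  A label outside the vocabulary whose row carries no
#'   fractional weights is a schema error.
#' @return A data frame of class `sample_sheet` with attributes `schema`,
#'   and for the panel schema `membership` (sample x cell-type weights),
#'   `cell_types` and `extra_types`.
#' @export
read_sample_sheet <- function(path, schema = c("panel", "cohort"),
                              control_types = character(),
                              cell_types = NULL) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"), stringsAsFactors = FALSE)
  as_sample_sheet(df, schema = schema, control_types = control_types,
                  cell_types = cell_types)
}

#' Build a sample sheet from a data frame
#'
#' @param df data frame with the columns described in [read_sample_sheet()].
#' @inheritParams read_sample_sheet
#' @return A `sample_sheet` data frame.
#' @export
as_sample_sheet <- function(df, schema = c("panel", "cohort"),
                            control_types = character(),
                            cell_types = NULL) {
  schema <- match.arg(schema)
  if (!"sample_id" %in% names(df))
    stop("sample sheet must have a 'sample_id' column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (!"chip_id" %in% names(df)) df$chip_id <- NA_character_
  df$chip_id <- as.character(df$chip_id)

  if (schema == "panel") {
    if (!"cell_type" %in% names(df))
      stop("panel sample sheet must have a 'cell_type' column", call. = FALSE)
    reserved <- c("sample_id", "cell_type", "chip_id")
    frac_cols <- setdiff(names(df), reserved)
    frac_cols <- frac_cols[vapply(df[frac_cols], is.numeric, logical(1))]
    labels <- unique(df$cell_type)
    pure_labels <- setdiff(labels, control_types)
    # a label is a cell type if it is used as a pure label or names a
    # fractional column; labels covered only by fractions stay out
    has_frac <- rep(FALSE, nrow(df))
    if (length(frac_cols) > 0)
      has_frac <- rowSums(!is.na(as.matrix(df[frac_cols]))) > 0
    if (is.null(cell_types))
      cell_types <- sort(unique(c(setdiff(pure_labels,
                                          df$cell_type[has_frac]),
                                  frac_cols)))
    unknown <- setdiff(df$cell_type[!has_frac], c(cell_types, control_types))
    if (length(unknown) > 0)
      stop("unknown cell_type label(s) without fractional membership: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    membership <- matrix(0, nrow(df), length(cell_types),
                         dimnames = list(df$sample_id, cell_types))
    for (i in seq_len(nrow(df))) {
      if (has_frac[i]) {
        w <- unlist(df[i, frac_cols])
        w[is.na(w)] <- 0
        membership[i, frac_cols] <- w
      } else if (df$cell_type[i] %in% cell_types) {
        membership[i, df$cell_type[i]] <- 1
      }
    }
    if (any(membership < 0 | membership > 1))
      stop("fractional membership weights must lie in [0,1]", call. = FALSE)
    rs <- rowSums(membership)
    if (any(rs > 1 + 1e-9))
      stop("membership weights of sample '",
           df$sample_id[which(rs > 1 + 1e-9)[1]], "' sum to ",
           format(max(rs)), " > 1", call. = FALSE)
    extra <- matrix(0, nrow(df), length(control_types),
                    dimnames = list(df$sample_id, control_types))
    for (ct in control_types) extra[df$cell_type == ct, ct] <- 1
    attr(df, "membership") <- membership
    attr(df, "cell_types") <- cell_types
    attr(df, "extra") <- extra
    attr(df, "extra_types") <- control_types
  } else {
    covar_cols <- setdiff(names(df), c("sample_id", "chip_id"))
    for (cc in covar_cols) {
      if (!is.numeric(df[[cc]]))
        stop("cohort covariate column '", cc, "' must be numeric ",
             "(code factors as indicators)", call. = FALSE)
    }
    attr(df, "covariates") <- covar_cols
  }
  attr(df, "schema") <- schema
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write an inference result as a coefficient table
#'
#' One row per term (intercept + each cell type) and covariate with columns
#' `Est`, `Bias2`, `SE0`, `SE1`, `SE2`, `p_value`, all in percentage points,
#' mirroring the usual presentation of population-level deconvolution
#' results.
#'
#' @param result an `inference_result` from [bootstrap_inference()] (after
#'   [wald_inference()]).
#' @param path output CSV path.
#' @param covariates which covariate columns to write; default all.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(result, path,
                                    covariates = colnames(result$est)) {
  stopifnot(inherits(result, "inference_result"))
  rows <- list()
  for (cv in covariates) {
    rows[[cv]] <- data.frame(
      covariate = cv,
      term = rownames(result$est),
      Est = result$est[, cv],
      Bias2 = result$bias2[, cv],
      SE0 = result$se0[, cv],
      SE1 = result$se1[, cv],
      SE2 = result$se2[, cv],
      p_value = result$p_values[, cv],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(covariates) == 0)
    tab <- data.frame(covariate = character(), term = character(),
                      Est = double(), Bias2 = double(), SE0 = double(),
                      SE1 = double(), SE2 = double(), p_value = double())
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a coefficient table written by [write_coefficient_table()]
#' @param path CSV path.
#' @return data frame with numeric statistic columns.
#' @export
read_coefficient_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  num_cols <- intersect(c("Est", "Bias2", "SE0", "SE1", "SE2", "p_value"),
                        names(tab))
  for (nc in num_cols) tab[[nc]] <- as.numeric(tab[[nc]])
  tab
}

#' Drop CpGs with missing values across data sets
#'
#' CpGs with any missing beta value in any of the supplied matrices are
#' excluded (imputation is deliberately not attempted); the number dropped
#' is reported via `message()`.
#'
#' @param ... one or more `beta_matrix` objects.
#' @return Character vector of CpG IDs complete in every matrix.
#' @export
complete_cpgs <- function(...) {
  mats <- list(...)
  ids <- Reduce(intersect, lapply(mats, rownames))
  keep <- ids
  for (m in mats) keep <- keep[rowSums(is.na(m[keep, , drop = FALSE])) == 0]
  dropped <- length(ids) - length(keep)
  if (dropped > 0)
    message(dropped, " CpG(s) dropped for missing values; ",
            length(keep), " retained")
  keep
}
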