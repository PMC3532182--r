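# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# tiny two-type reference profiles with well-separated CpGs
tiny_profiles <- function(m = 8, types = c("A", "B")) {
  B0 <- matrix(NA_real_, m, length(types),
               dimnames = list(sprintf("cg%02d", seq_len(m)), types))
  set.seed(401)
  for (j in seq_len(m)) {
    hi <- sample(c(TRUE, FALSE), length(types), replace = TRUE)
    if (all(hi) || !any(hi)) hi[1] <- !hi[1]
    B0[j, ] <- ifelse(hi, runif(1, 0.8, 0.95), runif(1, 0.05, 0.2))
  }
  B0
}

# panel beta matrix + sheet with k replicates per type and optional noise
tiny_panel <- function(B0, k = 3, noise_sd = 0, chips = NULL, seed = 42) {
  set.seed(seed)
  types <- colnames(B0)
  n <- k * length(types)
  ids <- sprintf("P%02d", seq_len(n))
  lab <- rep(types, each = k)
  Y <- B0[, lab, drop = FALSE] +
    matrix(rnorm(nrow(B0) * n, 0, noise_sd), nrow(B0), n)
  Y <- pmin(pmax(Y, 0), 1)
  colnames(Y) <- ids
  df <- data.frame(sample_id = ids, cell_type = lab,
                   stringsAsFactors = FALSE)
  if (!is.null(chips)) df$chip_id <- chips
  list(beta = beta_matrix(Y), sheet = as_sample_sheet(df, "panel"))
}

# a fitted reference_fit for the tiny profiles
tiny_reference <- function(B0 = tiny_profiles(), k = 3, noise_sd = 0, ...) {
  pan <- tiny_panel(B0, k = k, noise_sd = noise_sd, ...)
  fit_reference_model(pan$beta, pan$sheet)
}

# cohort beta matrix + sheet: mixtures of B0 columns + noise, case/control
tiny_cohort <- function(B0, weights, case = NULL, noise_sd = 0, seed = 7,
                        intercept_shift = 0) {
  set.seed(seed)
  n <- nrow(weights)
  ids <- sprintf("S%03d", seq_len(n))
  Y <- B0 %*% t(weights) + intercept_shift +
    matrix(rnorm(nrow(B0) * n, 0, noise_sd), nrow(B0), n)
  Y <- pmin(pmax(Y, 0), 1)
  colnames(Y) <- ids
  df <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(case)) df$case <- case
  list(beta = beta_matrix(Y), sheet = as_sample_sheet(df, "cohort"))
}

# minimal hand-built target fit (for projection tests that only need B1)
stub_target <- function(B1, cpg_ids = rownames(B1), Z = NULL, SSe = 0,
                        Y = NULL) {
  n <- if (is.null(Z)) 2 else nrow(Z)
  if (is.null(Z)) Z <- cbind(`(Intercept)` = rep(1, n))
  structure(list(cpg_ids = cpg_ids, B1 = B1, Z = Z, SSe = SSe,
                 per_cpg_resid_var = rep(0, nrow(B1)),
                 sample_ids = rownames(Z), chip_ids = rep(NA, n),
                 mixed = FALSE, Y = Y),
            class = "target_fit")
}

# brute-force least squares via explicit normal equations
normal_eq <- function(X, Y) solve(t(X) %*% X) %*% t(X) %*% Y

# two-type constrained-projection oracle: dense grid over the non-negative
# quadrant with the free intercept profiled out analytically, refined by a
# second local grid so the oracle itself is accurate to ~1e-5
grid_oracle_2type <- function(X, y, step = 1e-3) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  G <- crossprod(Xc)
  a <- crossprod(Xc, yc)
  eval_grid <- function(g1, g2) {
    rss <- outer(g1^2 * G[1, 1] - 2 * g1 * a[1],
                 g2^2 * G[2, 2] - 2 * g2 * a[2], "+") +
      2 * G[1, 2] * outer(g1, g2)
    best <- arrayInd(which.min(rss), dim(rss))
    c(g1[best[1]], g2[best[2]])
  }
  coarse <- eval_grid(seq(0, 1, by = step), seq(0, 1, by = step))
  fine1 <- seq(max(0, coarse[1] - 2 * step), coarse[1] + 2 * step,
               by = step / 100)
  fine2 <- seq(max(0, coarse[2] - 2 * step), coarse[2] + 2 * step,
               by = step / 100)
  eval_grid(fine1, fine2)
}

# write a beta matrix to CSV the way a user would supply it
write_beta_csv <- function(values, path) {
  df <- data.frame(cpg_id = rownames(values), values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
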