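test_that("naive SEs match the textbook OLS formula and vanish when U = 0", {
  set.seed(19)
  B0 <- tiny_profiles(m = 5)
  ref <- tiny_reference(B0, k = 1, noise_sd = 0)
  Bt <- cbind(1, ref$B0)
  # U = 0: B1 exactly in the reference space
  B1 <- Bt %*% rbind(c(0, 0), c(0.4, 0.1), c(0.6, -0.1))
  colnames(B1) <- c("(Intercept)", "case")
  tg <- stub_target(B1, ref$cpg_ids)
  proj <- project_onto_reference(ref, tg)
  expect_equal(max(naive_se(ref, tg, proj)), 0, tolerance = 1e-10)

  B1n <- B1 + matrix(rnorm(10, 0, 0.02), 5, 2)
  proj_n <- project_onto_reference(ref, stub_target(B1n, ref$cpg_ids))
  se <- naive_se(ref, stub_target(B1n, ref$cpg_ids), proj_n)
  # independent oracle: sqrt(diag((Bt'Bt)^-1) * ||u_k||^2 / (m - p)) * 100
  M <- solve(t(Bt) %*% Bt)
  for (k in 1:2) {
    sig2 <- sum(proj_n$U[, k]^2) / (5 - 3)
    expect_equal(unname(se[, k]), unname(sqrt(diag(M) * sig2) * 100),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap SE of an embedded mean matches sd/sqrt(n)", {
  # reference with one 'cell type' whose profile is (0, 1): the projection
  # coefficient of an intercept-only cohort fit is then exactly the sample
  # mean of the second CpG, so SE1 must reproduce the classical sd/sqrt(n)
  Y0 <- rbind(cg01 = c(0, 0), cg02 = c(1, 1))
  colnames(Y0) <- c("P01", "P02")
  sheet0 <- as_sample_sheet(data.frame(sample_id = c("P01", "P02"),
                                       cell_type = "A",
                                       stringsAsFactors = FALSE), "panel")
  ref <- fit_reference_model(beta_matrix(Y0), sheet0)
  set.seed(55)
  n <- 40
  x <- runif(n, 0.2, 0.8)
  Y1 <- rbind(cg01 = rep(0, n), cg02 = x)
  colnames(Y1) <- sprintf("S%03d", 1:n)
  coh_sheet <- as_sample_sheet(data.frame(sample_id = colnames(Y1),
                                          stringsAsFactors = FALSE),
                               "cohort")
  tg <- fit_target_model(beta_matrix(Y1), coh_sheet)
  inf <- bootstrap_inference(ref, tg, n_boot = 1000, seed = 77)
  expect_equal(inf$est["A", 1], 100 * mean(x), tolerance = 1e-8)
  se_oracle <- 100 * sd(x) / sqrt(n)
  # 3 Monte-Carlo SEs of a bootstrap SD estimate: se/sqrt(2*(B-1))
  mc_tol <- 3 * se_oracle / sqrt(2 * 999)
  expect_lt(abs(inf$se1["A", 1] - se_oracle), mc_tol + 0.02 * se_oracle)
  # noiseless reference => parametric perturbation is degenerate: SE2 = SE1
  expect_equal(inf$se2, inf$se1, tolerance = 1e-12)
})

test_that("zero-noise identical cohort gives (near) zero bootstrap SE", {
  B0 <- tiny_profiles()
  ref <- tiny_reference(B0, k = 1, noise_sd = 0)
  w <- matrix(rep(c(0.45, 0.55), each = 8), 8, 2)
  coh <- tiny_cohort(B0, w, case = rep(0:1, each = 4), noise_sd = 0)
  tg <- fit_target_model(coh$beta, coh$sheet)
  inf <- bootstrap_inference(ref, tg, n_boot = 50, seed = 1)
  expect_lt(max(inf$se1), 1e-8)
})

test_that("bias correction arithmetic and Wald construction are exact", {
  # worked case-control arithmetic: corrected = Est - Bias2, z = Est/SE2
  est <- matrix(c(-9.08, 3.06), 2, 1,
                dimnames = list(c("CD4T", "CD8T"), "case"))
  bias2 <- matrix(c(1.32, -1.46), 2, 1, dimnames = dimnames(est))
  se2 <- matrix(c(1.39, 1.27), 2, 1, dimnames = dimnames(est))
  stub <- structure(list(est = est, se0 = est * NA, se1 = est * NA,
                         se2 = se2, bias2 = bias2,
                         est_corrected = est - bias2,
                         n_boot = 250, mode = "double"),
                    class = "inference_result")
  stub <- wald_inference(stub)
  expect_equal(stub$est_corrected["CD4T", "case"], -10.40, tolerance = 1e-12)
  expect_lt(abs(stub$p_values["CD8T", "case"] - 0.016), 1e-3)
  expect_equal(stub$ci_lower["CD8T", "case"],
               (3.06 + 1.46) - qnorm(0.975) * 1.27, tolerance = 1e-12)
})

test_that("wald edge cases: zero estimate and zero SE", {
  est <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "case"))
  se2 <- matrix(c(1, 0), 2, 1, dimnames = dimnames(est))
  stub <- structure(list(est = est, se2 = se2, bias2 = est * 0,
                         est_corrected = est, mode = "double"),
                    class = "inference_result")
  expect_warning(stub <- wald_inference(stub), "zero bootstrap SE")
  expect_equal(stub$p_values["a", "case"], 1)
  expect_equal(stub$p_values["b", "case"], 0)
  # z = 1.96 -> p = 0.05
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

test_that("bootstrap results are bit-reproducible and converge in n_boot", {
  B0 <- tiny_profiles(m = 10)
  ref <- tiny_reference(B0, k = 3, noise_sd = 0.02, seed = 9)
  set.seed(101)
  w <- matrix(runif(48, 0.2, 0.8), 24, 2); w <- w / rowSums(w)
  coh <- tiny_cohort(B0, w, case = rep(0:1, each = 12), noise_sd = 0.02)
  tg <- fit_target_model(coh$beta, coh$sheet)
  a <- bootstrap_inference(ref, tg, n_boot = 60, seed = 42)
  b <- bootstrap_inference(ref, tg, n_boot = 60, seed = 42)
  expect_identical(a$est, b$est)
  expect_identical(a$se2, b$se2)
  expect_identical(a$replicates, b$replicates)
  # SE estimates stabilise between 250 and 1000 replicates: each entry's
  # relative change is bounded by 3 Monte-Carlo SDs of a bootstrap SD,
  # sqrt(1/(2*249) + 1/(2*999)) ~ 5.2%, derived a priori
  s250 <- bootstrap_inference(ref, tg, n_boot = 250, seed = 7)
  s1000 <- bootstrap_inference(ref, tg, n_boot = 1000, seed = 8)
  rel <- abs(s250$se2 - s1000$se2) / s1000$se2
  mc_sd <- sqrt(1 / (2 * 249) + 1 / (2 * 999))
  expect_lt(max(rel), 3 * mc_sd)
  expect_lt(stats::median(rel), 1.5 * mc_sd)
})

test_that("transform_gamma: identity, and group composition equals a refit", {
  B0 <- tiny_profiles(m = 10)
  ref <- tiny_reference(B0, k = 2, noise_sd = 0.01, seed = 12)
  set.seed(301)
  n <- 20
  w <- matrix(runif(2 * n, 0.2, 0.8), n, 2); w <- w / rowSums(w)
  case <- rep(0:1, each = n / 2)
  coh <- tiny_cohort(B0, w, case = case, noise_sd = 0.02)
  tg <- fit_target_model(coh$beta, coh$sheet)
  inf <- bootstrap_inference(ref, tg, n_boot = 40, seed = 5)

  ident <- transform_gamma(inf, diag(2))
  expect_equal(unname(ident$est), unname(inf$est), tolerance = 1e-12)
  expect_equal(unname(ident$se2), unname(inf$se2), tolerance = 1e-12)

  # intercept + case column = case-group composition from a direct refit
  L <- cbind(case_group = c(1, 1))
  tr <- transform_gamma(inf, L)
  case_beta <- beta_matrix(unclass(coh$beta)[, case == 1])
  case_sheet <- as_sample_sheet(
    data.frame(sample_id = colnames(case_beta), stringsAsFactors = FALSE),
    "cohort")
  tg_case <- fit_target_model(case_beta, case_sheet)
  refit <- project_onto_reference(ref, tg_case)
  expect_equal(unname(tr$est[, 1]), unname(refit$coef[, 1] * 100),
               tolerance = 1e-8)
  expect_error(transform_gamma(inf, diag(3)), "must have 2 rows")
})

test_that("sensitivity alpha equals the least-squares oracle", {
  B0 <- tiny_profiles(m = 10)
  ref <- tiny_reference(B0, k = 1, noise_sd = 0)
  alpha0 <- c(A = 0.03, B = -0.02)
  delta <- drop(ref$B0 %*% alpha0)
  res <- sensitivity_alpha(ref, delta)
  expect_equal(res$alpha, 100 * alpha0, tolerance = 1e-10)
  # orthogonal delta -> alpha = 0
  set.seed(8)
  dperp <- drop(qr.resid(qr(ref$B0), rnorm(10)))
  expect_lt(max(abs(sensitivity_alpha(ref, dperp)$alpha)), 1e-8)
  # random delta -> brute-force normal equations
  d <- runif(10, -0.05, 0.05)
  oracle <- 100 * drop(normal_eq(ref$B0, matrix(d)))
  expect_equal(unname(sensitivity_alpha(ref, d)$alpha), unname(oracle),
               tolerance = 1e-10)
  expect_error(sensitivity_alpha(ref, d[-1]), "length")
})
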