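test_that("scenario specs encode the named designs", {
  s1 <- scenario_spec("StrongAltI")
  expect_equal(unname(100 * s1$case_deltas[c("Gran", "CD4T", "CD8T")]),
               c(8, -4, -2))
  expect_equal(s1$theta, 0)
  s2 <- scenario_spec("StrongAltII")
  expect_equal(unname(100 * s2$case_deltas[c("Gran", "CD4T", "CD8T")]),
               c(8, -6, 0))
  sm <- scenario_spec("MixedAlt")
  expect_equal(unname(sm$case_deltas), unname(s1$case_deltas) / 2)
  expect_equal(sm$theta, 0.5)
  expect_equal(scenario_spec("MixedNull")$theta, 1)
  expect_equal(sum(s1$control_mix), 0.95, tolerance = 1e-12)
  expect_true(all(scenario_spec("StrongNull")$case_deltas == 0))
  expect_error(scenario_spec("StrongAltI", n1 = 7), "even")
})

test_that("reference profiles are discriminating and U is orthogonal", {
  pr <- simulate_reference_profiles(m = 60, seed = 31)
  Bt <- cbind(1, pr$B0)
  expect_lt(max(abs(crossprod(Bt, pr$U))), 1e-10)
  # all pairwise cell-type profile distances strictly positive
  D <- as.matrix(dist(t(pr$B0)))
  expect_gt(min(D[upper.tri(D)]), 0)
  expect_true(all(pr$B0 >= 0 & pr$B0 <= 1))
  expect_true(all(pr$sigma >= 0.02 & pr$sigma <= 0.05))
  expect_error(simulate_reference_profiles(m = 5), "at least")
})

test_that("simulated panels honour counts, noise and Pan-T fractions", {
  pr <- simulate_reference_profiles(m = 30, seed = 41)
  pan <- simulate_validation_panel(pr, seed = 42, noise_sd = 0)
  expect_equal(ncol(pan$beta), 50)  # 5+10+5+15+5+8+2
  mem <- attr(pan$sheet, "membership")
  pure <- pan$sheet$cell_type != "PanT"
  for (i in which(pure)[1:5])
    expect_equal(unname(unclass(pan$beta)[, i]),
                 unname(pr$B0 %*% mem[i, ])[, 1], tolerance = 1e-12)
  pant <- which(pan$sheet$cell_type == "PanT")[1]
  expect_equal(unname(mem[pant, c("CD4T", "CD8T")]), c(0.65, 0.35))

  # law of large numbers: per-type means approach B0 at n = 200 per type
  big <- simulate_validation_panel(
    pr, panel_spec(c(Bcell = 200, Gran = 200, Mono = 200, NK = 200,
                     PanT = 1, CD4T = 200, CD8T = 200)), seed = 43)
  for (ty in c("Bcell", "Gran")) {
    idx <- big$sheet$cell_type == ty
    mean_obs <- rowMeans(unclass(big$beta)[, idx])
    tol <- 3 * pr$sigma / sqrt(200)
    # clipping to [0,1] can shave a little off near-boundary CpGs
    expect_lt(mean(abs(mean_obs - pr$B0[, ty]) > tol + 0.01), 0.05)
  }
})

test_that("Dirichlet mixture weights match their closed-form moments", {
  pr <- simulate_reference_profiles(m = 20, seed = 51)
  sc <- scenario_spec("StrongAltI", n1 = 10000)
  coh <- simulate_target_cohort(pr, sc, seed = 52)
  W <- coh$weights
  ctrl <- W[1:5000, ]
  case <- W[5001:10000, ]
  s0 <- sum(sc$control_mix)
  s1 <- sum(sc$case_mix)
  # means are the stated compositions exactly (scaled-simplex construction)
  mc_se <- sqrt(sc$control_mix * s0 / 100) / sqrt(5000)  # generous bound
  expect_lt(max(abs(colMeans(ctrl) - sc$control_mix) / (3 * mc_se + 1e-4)), 1)
  expect_lt(max(abs(colMeans(case) - sc$case_mix)), 0.01)
  # closed-form variance: s^2 * p(1-p)/(precision+1), p = mean/s
  p <- sc$control_mix / s0
  v_expected <- s0^2 * p * (1 - p) / (sc$dirichlet_precision + 1)
  expect_equal(unname(apply(ctrl, 2, var)), unname(v_expected),
               tolerance = 0.1)
  # case-control weight difference equals the scenario deltas; a priori
  # MC bound: 3 * max weight SD * sqrt(2/5000) ~ 0.003
  expect_lt(max(abs((colMeans(case) - colMeans(ctrl)) - sc$case_deltas)),
            0.003)
})

test_that("noisy mixtures widen the weight distribution as specified", {
  pr <- simulate_reference_profiles(m = 20, seed = 61)
  sc10 <- scenario_spec("StrongNull", n1 = 4000, dirichlet_precision = 10)
  coh <- simulate_target_cohort(pr, sc10, seed = 62)
  p <- sc10$control_mix / sum(sc10$control_mix)
  v_expected <- sum(sc10$control_mix)^2 * p * (1 - p) / 11
  expect_equal(unname(apply(coh$weights[1:2000, ], 2, var)),
               unname(v_expected), tolerance = 0.12)
})

test_that("mixed-null case shift is orthogonal to the reference space", {
  pr <- simulate_reference_profiles(m = 40, seed = 71)
  sc <- scenario_spec("MixedNull", n1 = 2000)
  coh <- simulate_target_cohort(pr, sc, seed = 72)
  Y <- unclass(coh$beta)
  diff <- rowMeans(Y[, 1001:2000]) - rowMeans(Y[, 1:1000])
  # the systematic case/control difference projects to ~0 cell-type shift
  proj <- qr.coef(qr(cbind(1, pr$B0)), diff)
  expect_lt(max(abs(proj[-1])), 0.01)
  # but the shift itself is present (theta = 1)
  expect_gt(sqrt(sum(diff^2)), 0.05)
})

test_that("discriminating CpGs outrank constant decoys", {
  hits <- 0L
  n_runs <- 40
  for (s in seq_len(n_runs)) {
    pr <- simulate_reference_profiles(m = 12, seed = 100 + s)
    # append 4 decoy CpGs with no cell-type signal
    B0d <- rbind(pr$B0,
                 matrix(0.5, 4, 6,
                        dimnames = list(sprintf("decoy%02d", 1:4),
                                        colnames(pr$B0))))
    prd <- list(B0 = B0d, mu1 = c(pr$mu1, rep(0.5, 4)),
                U = rbind(pr$U, matrix(0, 4, 2)),
                sigma = c(pr$sigma, rep(0.03, 4)),
                cell_types = pr$cell_types)
    pan <- simulate_validation_panel(prd, seed = 200 + s)
    fit <- fit_reference_model(pan$beta, pan$sheet)
    top <- select_top_cpgs(rank_cpgs(fit), 12)
    if (!any(startsWith(top, "decoy"))) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.99)
})

test_that("run_scenario is seed-deterministic and aggregates correctly", {
  sc <- scenario_spec("StrongAltI", n1 = 60, n_boot = 10, n_reps = 4)
  a <- run_scenario(sc, seed = 9)
  b <- run_scenario(sc, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$estimates, b$estimates)
  expect_equal(nrow(a$summary), 6)
  expect_named(a$summary,
               c("cell_type", "truth", "est", "sd", "se0", "se1", "se2",
                 "pow(0.05)", "pow(0.01)"))
  expect_equal(a$summary$truth, c(0, -4, -2, 8, 0, 0))
  expect_true(all(a$summary$`pow(0.05)` >= 0 & a$summary$`pow(0.05)` <= 1))
  expect_equal(unname(colMeans(a$estimates)), a$summary$est)
})

test_that("scaled-down replicate runs agree with larger ones", {
  # self-consistency: a 60-replicate run reproduces the mean estimates of
  # a 200-replicate run within 3 combined Monte-Carlo SEs
  sc <- scenario_spec("StrongAltI", n1 = 100, n_boot = 20)
  pr <- simulate_reference_profiles(seed = 88)
  small <- run_scenario(sc, n_reps = 60, seed = 1, profiles = pr)
  large <- run_scenario(sc, n_reps = 200, seed = 2, profiles = pr)
  mc <- sqrt(small$summary$sd^2 / small$n_reps +
             large$summary$sd^2 / large$n_reps)
  expect_true(all(abs(small$summary$est - large$summary$est) <= 3 * mc))
})
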