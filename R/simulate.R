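SIM_CELL_TYPES <- c("Bcell", "CD4T", "CD8T", "Gran", "Mono", "NK")

#' Specify a simulation scenario
#'
#' Encodes the named case-control scenarios of the simulation study.  The
#' control blood composition is 7% B cells, 62% granulocytes, 6%
#' monocytes, 2% NK cells, 13% T cells (split 65/35 into CD4+/CD8+), and
#' 5% unspecified cells carrying the unsorted pan-T profile; the printed
#' components sum to 0.95, the remainder of the methylation signal being
#' carried by the non-cell residual term xi (see the methods vignette).
#' Per-subject mixture weights are Dirichlet distributed around these
#' means with the given precision (100 = "precise", 10 = "noisy").
#'
#' Case scenarios, deltas in absolute percentage points:
#' * `StrongAltI`: granulocytes +8, CD4+ -4, CD8+ -2 (theta = 0)
#' * `StrongAltII`: granulocytes +8, CD4+ -6 (theta = 0)
#' * `MixedAlt`: half the StrongAltI effects (theta = 0.5)
#' * `StrongNull`: no changes, no residual difference (theta = 0)
#' * `MixedNull`: no mixture changes; a case-only residual shift
#'   orthogonal to the cell profiles (theta = 1)
#'
#' @param name scenario name (see above).
#' @param n1 cohort size (half cases, half controls); 100, 200 or 500.
#' @param dirichlet_precision Dirichlet precision (100 or 10).
#' @param n_boot bootstrap iterations per replicate (default 50).
#' @param n_reps number of simulation replicates (default 1000).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("StrongAltI", "StrongAltII", "MixedAlt",
                                   "StrongNull", "MixedNull"),
                          n1 = 200, dirichlet_precision = 100,
                          n_boot = 50, n_reps = 1000) {
  name <- match.arg(name)
  if (n1 < 4 || n1 %% 2 != 0)
    stop("n1 must be an even number >= 4", call. = FALSE)
  if (dirichlet_precision <= 0)
    stop("dirichlet_precision must be positive", call. = FALSE)
  control_mix <- c(Bcell = 0.07, CD4T = 0.13 * 0.65, CD8T = 0.13 * 0.35,
                   Gran = 0.62, Mono = 0.06, NK = 0.02,
                   Unspecified = 0.05)
  deltas <- c(Bcell = 0, CD4T = 0, CD8T = 0, Gran = 0, Mono = 0, NK = 0,
              Unspecified = 0)
  theta <- 0
  xi_case_mult <- 0.1
  if (name == "StrongAltI") {
    deltas[c("Gran", "CD4T", "CD8T")] <- c(0.08, -0.04, -0.02)
    xi_case_mult <- 0.08
  } else if (name == "StrongAltII") {
    deltas[c("Gran", "CD4T")] <- c(0.08, -0.06)
    xi_case_mult <- 0.08
  } else if (name == "MixedAlt") {
    deltas[c("Gran", "CD4T", "CD8T")] <- c(0.04, -0.02, -0.01)
    theta <- 0.5
    xi_case_mult <- 0.09
  } else if (name == "MixedNull") {
    theta <- 1
  }
  case_mix <- control_mix + deltas
  if (any(case_mix < 0))
    stop("case mixture has a negative component", call. = FALSE)
  structure(list(
    name = name, n1 = n1,
    control_mix = control_mix, case_deltas = deltas, case_mix = case_mix,
    dirichlet_precision = dirichlet_precision,
    theta = theta,
    xi_control_mult = 0.1, xi_case_mult = xi_case_mult,
    u_scale = 10,
    n_boot = n_boot, n_reps = n_reps,
    truth = 100 * deltas[SIM_CELL_TYPES]
  ), class = "scenario_spec")
}

#' Specify the synthetic purified-cell panel
#'
#' Default counts: 5 B cells, 10 granulocytes, 5 monocytes, 15 NK, 5
#' unsorted Pan-T (fractional CD4/CD8 membership 0.65/0.35), 8 CD4+, 2
#' CD8+ -- 50 samples in total.
#'
#' @param samples_per_type named integer vector of panel sample counts.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(samples_per_type = c(Bcell = 5, Gran = 10, Mono = 5,
                                            NK = 15, PanT = 5, CD4T = 8,
                                            CD8T = 2)) {
  if (any(samples_per_type < 1))
    stop("all panel sample counts must be >= 1", call. = FALSE)
  structure(list(samples_per_type = samples_per_type), class = "panel_spec")
}

#' Generate synthetic cell-type reference profiles
#'
#' Emulates cell-type-discriminating CpGs on a bead array: each CpG is
#' nearly unmethylated (beta ~ 0.05--0.20) or nearly methylated (beta ~
#' 0.75--0.95) in each cell type, with at least one type discordant, plus
#' small type-specific jitter.  Also generated: a whole-blood-like
#' intercept profile `mu1` (the control mixture of the profiles), columns
#' `U` orthogonalised against the column space of `(1, B0)` standing in
#' for non-cell-mediated covariate effects, and per-CpG noise standard
#' deviations.
#'
#' @param m number of CpGs (>= d0 + 2; default 100, the usual signature
#'   size).
#' @param seed optional integer seed.
#' @param sd_range range of per-CpG noise SDs on the beta scale (default
#'   0.02--0.05, typical array-level technical + biological variation).
#' @param u_norm Euclidean norm given to each U column (default 0.01,
#'   emulating the magnitude of fitted linking-regression residuals).
#' @param n_u number of U columns (default 2; the first plays the role of
#'   the case-covariate column).
#' @return List with `B0` (m x 6, types Bcell, CD4T, CD8T, Gran, Mono,
#'   NK), `mu1`, `U`, `sigma`, `cell_types`.
#' @export
simulate_reference_profiles <- function(m = 100, seed = NULL,
                                        sd_range = c(0.02, 0.05),
                                        u_norm = 0.01, n_u = 2) {
  d0 <- length(SIM_CELL_TYPES)
  if (m < d0 + 2)
    stop("m must be at least d0 + 2 = ", d0 + 2, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  B0 <- matrix(NA_real_, m, d0, dimnames = list(sprintf("cg%06d", seq_len(m)),
                                                SIM_CELL_TYPES))
  for (j in seq_len(m)) {
    repeat {
      hi <- stats::runif(d0) < 0.5
      if (any(hi) && !all(hi)) break
    }
    h <- stats::runif(1, 0.75, 0.95)
    l <- stats::runif(1, 0.05, 0.20)
    B0[j, ] <- ifelse(hi, h, l) + stats::rnorm(d0, 0, 0.02)
  }
  B0 <- pmin(pmax(B0, 0), 1)
  mix <- scenario_spec("StrongNull")$control_mix
  w6 <- mix[SIM_CELL_TYPES]
  w6["CD4T"] <- w6["CD4T"] + 0.65 * mix["Unspecified"]
  w6["CD8T"] <- w6["CD8T"] + 0.35 * mix["Unspecified"]
  w6 <- w6 / sum(w6)
  mu1 <- drop(B0 %*% w6)
  Bt <- cbind(1, B0)
  U <- matrix(stats::rnorm(m * n_u), m, n_u,
              dimnames = list(rownames(B0),
                              paste0("u", seq_len(n_u))))
  U <- qr.resid(qr(Bt), U)
  U <- sweep(U, 2, sqrt(colSums(U^2)) / u_norm, "/")
  sigma <- stats::runif(m, sd_range[1], sd_range[2])
  list(B0 = B0, mu1 = mu1, U = U, sigma = sigma,
       cell_types = SIM_CELL_TYPES)
}

#' Simulate a purified-cell validation panel
#'
#' Each panel sample is its cell type's profile plus per-CpG normal noise,
#' clipped to \[0,1\]; Pan-T samples are drawn from the 0.65/0.35 CD4/CD8
#' blend and enter the sample sheet with fractional membership.
#'
#' @param profiles output of [simulate_reference_profiles()].
#' @param spec a [panel_spec()].
#' @param seed optional integer seed.
#' @param noise_sd per-CpG noise SDs; default the profile-level `sigma`
#'   (0 gives a noiseless panel).
#' @return List with `beta` (a [beta_matrix()]) and `sheet` (panel-schema
#'   `sample_sheet`).
#' @export
simulate_validation_panel <- function(profiles, spec = panel_spec(),
                                      seed = NULL, noise_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- profiles$sigma
  m <- nrow(profiles$B0)
  noise_sd <- rep_len(noise_sd, m)
  counts <- spec$samples_per_type
  n0 <- sum(counts)
  types <- rep(names(counts), counts)
  ids <- sprintf("P%03d", seq_len(n0))
  membership <- matrix(0, n0, length(SIM_CELL_TYPES),
                       dimnames = list(ids, SIM_CELL_TYPES))
  for (i in seq_len(n0)) {
    if (types[i] == "PanT") {
      membership[i, c("CD4T", "CD8T")] <- c(0.65, 0.35)
    } else {
      membership[i, types[i]] <- 1
    }
  }
  mean_beta <- profiles$B0 %*% t(membership)
  Y <- mean_beta + matrix(stats::rnorm(m * n0, 0, noise_sd), m, n0)
  Y <- pmin(pmax(Y, 0), 1)
  beta <- beta_matrix(Y, cpg_ids = rownames(profiles$B0), sample_ids = ids)
  df <- data.frame(sample_id = ids, cell_type = types,
                   CD4T = ifelse(types == "PanT", 0.65, NA_real_),
                   CD8T = ifelse(types == "PanT", 0.35, NA_real_),
                   stringsAsFactors = FALSE)
  sheet <- as_sample_sheet(df, schema = "panel")
  list(beta = beta, sheet = sheet)
}

# Dirichlet mixture weights with means exactly equal to `mean_wts`
# (which may sum to s != 1): draws on the simplex are rescaled by s.
rdirichlet_scaled <- function(n, mean_wts, precision) {
  s <- sum(mean_wts)
  alpha <- precision * mean_wts / s
  G <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  W <- G / rowSums(G) * s
  colnames(W) <- names(mean_wts)
  W
}

#' Simulate a case-control whole-blood cohort
#'
#' Per subject, mixture weights over the seven components (six cell types
#' plus the unspecified pan-T-like remainder) are Dirichlet distributed
#' with mean equal to the scenario composition; the methylation profile is
#' the weighted blend of cell-type profiles plus the non-cell residual
#' term xi and per-CpG normal noise, clipped to \[0,1\].  Controls get
#' `xi = 0.1 * mu1`; the case-control difference in xi is orthogonalised
#' against the column space of `(1, B0)` (the identifiability condition of
#' the linking model -- see the methods vignette) and includes the
#' `u_scale * theta * U` shift for mixed scenarios.
#'
#' @param profiles output of [simulate_reference_profiles()].
#' @param scenario a [scenario_spec()].
#' @param seed optional integer seed.
#' @return List with `beta`, `sheet` (cohort schema, covariate `case`),
#'   `weights` (n1 x 7 realised mixture weights), `truth` (the scenario's
#'   true case effects, percentage points).
#' @export
simulate_target_cohort <- function(profiles, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(profiles$B0)
  n1 <- scenario$n1
  n_half <- n1 / 2
  case <- rep(c(0, 1), each = n_half)
  ids <- sprintf("S%04d", seq_len(n1))

  W0 <- rdirichlet_scaled(n_half, scenario$control_mix,
                          scenario$dirichlet_precision)
  W1 <- rdirichlet_scaled(n_half, scenario$case_mix,
                          scenario$dirichlet_precision)
  W <- rbind(W0, W1)
  rownames(W) <- ids

  B7 <- cbind(profiles$B0,
              Unspecified = 0.65 * profiles$B0[, "CD4T"] +
                            0.35 * profiles$B0[, "CD8T"])
  xi0 <- scenario$xi_control_mult * profiles$mu1
  delta_xi <- (scenario$xi_case_mult - scenario$xi_control_mult) *
    profiles$mu1 +
    scenario$u_scale * scenario$theta * profiles$U[, 1]
  delta_xi <- drop(qr.resid(qr(cbind(1, profiles$B0)), delta_xi))
  Xi <- outer(xi0, rep(1, n1)) + outer(delta_xi, case)
  Y <- B7 %*% t(W) + Xi +
    matrix(stats::rnorm(m * n1, 0, profiles$sigma), m, n1)
  Y <- pmin(pmax(Y, 0), 1)
  beta <- beta_matrix(Y, cpg_ids = rownames(profiles$B0), sample_ids = ids)
  sheet <- as_sample_sheet(data.frame(sample_id = ids, case = case,
                                      stringsAsFactors = FALSE),
                           schema = "cohort")
  list(beta = beta, sheet = sheet, weights = W, truth = scenario$truth)
}

#' Run a full simulation scenario
#'
#' Per replicate: simulate a purified panel and a case-control cohort, fit
#' the reference and target models, project, and run the double bootstrap;
#' record the case-column estimates, standard errors and p-values for each
#' cell type.  Results are aggregated as truth, mean estimate, replicate
#' SD, median SE0/SE1/SE2 and rejection proportions at the requested
#' alpha levels.
#'
#' @param scenario a [scenario_spec()].
#' @param panel a [panel_spec()].
#' @param n_reps,n_boot override the scenario's replicate/bootstrap counts.
#' @param seed integer seed for the whole run (reference profiles are
#'   generated once from it; replicates consume the stream sequentially).
#' @param alpha significance levels for rejection proportions.
#' @param profiles optionally, pre-generated reference profiles (shared
#'   across scenarios of one study).
#' @return Object of class `scenario_result`: `summary` data frame (one
#'   row per cell type), the per-replicate `estimates`, `se2` and
#'   `p_values` matrices, and run metadata.  A replicate failure rate
#'   above 5% is an error.
#' @export
run_scenario <- function(scenario, panel = panel_spec(),
                         n_reps = scenario$n_reps,
                         n_boot = scenario$n_boot,
                         seed = NULL, alpha = c(0.05, 0.01),
                         profiles = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profiles)) profiles <- simulate_reference_profiles()
  d0 <- length(profiles$cell_types)
  est <- se0 <- se1 <- se2 <- pv <- matrix(
    NA_real_, n_reps, d0, dimnames = list(NULL, profiles$cell_types))
  failures <- character()
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      pan <- simulate_validation_panel(profiles, panel)
      ref <- fit_reference_model(pan$beta, pan$sheet)
      coh <- simulate_target_cohort(profiles, scenario)
      target <- fit_target_model(coh$beta, coh$sheet)
      bootstrap_inference(ref, target, mode = "double", n_boot = n_boot)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    ct <- profiles$cell_types
    est[r, ] <- res$est[ct, "case"]
    se0[r, ] <- res$se0[ct, "case"]
    se1[r, ] <- res$se1[ct, "case"]
    se2[r, ] <- res$se2[ct, "case"]
    pv[r, ] <- res$p_values[ct, "case"]
  }
  if (length(failures) > 0.05 * n_reps)
    stop("scenario run failed: ", length(failures), "/", n_reps,
         " replicates errored; first error: ", failures[1], call. = FALSE)
  ok <- !is.na(est[, 1])
  summary <- data.frame(
    cell_type = profiles$cell_types,
    truth = unname(scenario$truth),
    est = colMeans(est[ok, , drop = FALSE]),
    sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
    se0 = apply(se0[ok, , drop = FALSE], 2, stats::median),
    se1 = apply(se1[ok, , drop = FALSE], 2, stats::median),
    se2 = apply(se2[ok, , drop = FALSE], 2, stats::median),
    row.names = NULL, stringsAsFactors = FALSE)
  for (a in alpha)
    summary[[sprintf("pow(%g)", a)]] <-
      colMeans(pv[ok, , drop = FALSE] < a)
  structure(list(
    summary = summary,
    estimates = est[ok, , drop = FALSE],
    se2 = se2[ok, , drop = FALSE],
    p_values = pv[ok, , drop = FALSE],
    scenario = scenario,
    n_reps = sum(ok),
    n_failed = length(failures),
    seed = seed
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("%s (theta = %g, precision = %g, n1 = %d): %d replicates, %d bootstraps\n",
              x$scenario$name, x$scenario$theta,
              x$scenario$dirichlet_precision, x$scenario$n1,
              x$n_reps, x$scenario$n_boot))
  print(cbind(x$summary[1], round(x$summary[-1], 3)), row.names = FALSE)
  invisible(x)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: n1 = %d, precision = %g, theta = %g, xi mult %g (case) / %g (control)\n",
              x$name, x$n1, x$dirichlet_precision, x$theta,
              x$xi_case_mult, x$xi_control_mult))
  cat("case deltas (pct points):\n")
  print(100 * x$case_deltas)
  invisible(x)
}
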