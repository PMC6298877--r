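# one moderately sized fitted cohort shared across the tests below
jm_test_cohort <- prepared_cohort(seed = 42, n = 250)
jm_test_data <- jm_prepare(jm_test_cohort, jm_spec())
jm_test_lmm <- jm_test_data$lmm_fit

test_params <- function(data, alpha = 0.25, gamma0 = 0.15,
                        kappa_level = -3) {
  lmm <- data$lmm_fit
  list(beta = unname(lmm$beta), D = lmm$D, sigma2 = lmm$sigma2,
       gamma0 = gamma0, alpha = alpha,
       kappa = rep(kappa_level, data$kb))
}

test_that("linear predictor reduces to closed forms", {
  basis <- jm_test_data$traj_basis
  pars <- list(beta = c(0.4, 0.9, -7, 0.2), gamma0 = 0.15, alpha = 0)
  # alpha = 0: only the baseline covariate contributes, constant in t
  lp <- linear_predictor(pars, c(0, 0, 0), 7.3, c(0.5, 2, 4),
                         "current", basis)
  expect_equal(lp, rep(0.15 * 7.3, 3))
  # constant trajectory, cumulative: gamma0 w + alpha m t
  pars2 <- list(beta = c(1.2, 0, 0, 0), gamma0 = 0.1, alpha = 0.3)
  lp2 <- linear_predictor(pars2, c(0, 0, 0), 7.0, c(1, 2.5),
                          "cumulative", basis)
  expect_equal(lp2, 0.1 * 7.0 + 0.3 * 1.2 * c(1, 2.5))
  # spline trajectory, cumulative association vs a trapezoid rule
  pars3 <- list(beta = c(0.4, 0.9, -7, 0.2), gamma0 = 0, alpha = 1)
  b3 <- c(0.1, -0.3, 1.2)
  tt <- seq(0, 2.5, length.out = 10001)
  m <- drop(cbind(1, ncs_eval(basis, tt), 7.1) %*% pars3$beta) +
    drop(cbind(1, ncs_eval(basis, tt)) %*% b3)
  trap <- sum((m[-1] + m[-length(m)]) / 2 * diff(tt))
  lp3 <- linear_predictor(pars3, b3, 7.1, 2.5, "cumulative", basis)
  expect_lt(abs(lp3 - trap) / abs(trap), 1e-6)
})

test_that("joint likelihood factorizes at alpha = 0", {
  pars <- test_params(jm_test_data, alpha = 0)
  ll_joint <- sum(subject_loglik(jm_test_data, pars))
  resp <- suppressMessages(compute_response(jm_test_cohort))
  ll_lmm <- lmm_loglik(resp, jm_test_data$traj_basis, pars$beta,
                       pars$D, pars$sigma2)
  # independent parametric PH log-likelihood with baseline covariate
  gl <- pracma::gaussLegendre(30, 0, 1)
  ev <- jm_test_data$events
  base <- jm_test_cohort$baseline
  ll_ph <- 0
  for (k in seq_len(nrow(ev))) {
    Tk <- ev$event_time_years[k]
    w <- base$baseline_hba1c_pct[match(ev$subject_id[k],
                                       base$subject_id)]
    lh <- function(t) {
      drop(bspline_eval(jm_test_data$surv_basis, t) %*% pars$kappa) +
        pars$gamma0 * w
    }
    H <- Tk * sum(gl$w * exp(lh(Tk * gl$x)))
    ll_ph <- ll_ph + ev$event_indicator[k] * lh(Tk) - H
  }
  expect_lt(abs(ll_joint - (ll_lmm + ll_ph)) / abs(ll_joint), 1e-5)
})

test_that("subject likelihood matches dense brute-force integration", {
  pars <- test_params(jm_test_data, alpha = 0.3)
  set.seed(99)
  pick <- sample(length(jm_test_data$subjects), 10)
  lli <- subject_loglik(jm_test_data, pars)
  for (i in pick) {
    bf <- brute_force_subject_loglik(jm_test_data$subjects[[i]], pars,
                                     d = 3, nodes_per_dim = 200)
    expect_lt(abs(lli[i] - bf) / abs(bf), 1e-5)
  }
})

test_that("the quadrature is converged in the node count", {
  pars <- test_params(jm_test_data, alpha = 0.3)
  d9 <- jm_prepare(jm_test_cohort, jm_spec(gh_points = 9),
                   lmm_fit = jm_test_lmm)
  d15 <- jm_prepare(jm_test_cohort, jm_spec(gh_points = 15),
                    lmm_fit = jm_test_lmm)
  l9 <- subject_loglik(d9, pars, subject_id = jm_test_data$subject_ids[5])
  l15 <- subject_loglik(d15, pars,
                        subject_id = jm_test_data$subject_ids[5])
  expect_lt(abs(l9 - l15), 1e-6)
})

test_that("the joint fit ascends from its two-stage start and is deterministic", {
  fit <- fit_joint_model(jm_test_cohort, jm_spec(), se = FALSE,
                         lmm_fit = jm_test_lmm)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$stage_loglik - 1e-6)
  fit2 <- fit_joint_model(jm_test_cohort, jm_spec(), se = FALSE,
                          lmm_fit = jm_test_lmm)
  expect_identical(fit$par, fit2$par)
  # the decoupled (alpha = 0) likelihood never beats the optimum
  par0 <- fit$par
  par0[length(jm_test_lmm$beta) + 9] <- 0  # alpha slot
  expect_gte(fit$loglik, brjoint:::jm_eval(par0, fit$data)$loglik)
})

test_that("standard errors derive from a symmetric curvature estimate", {
  fit <- fit_joint_model(jm_test_cohort, jm_spec(), se = TRUE,
                         lmm_fit = jm_test_lmm)
  expect_true(all(is.finite(fit$se[c("gamma0", "alpha")])))
  expect_gt(fit$se[["alpha"]], 0)
  V <- fit$vcov
  expect_equal(V, t(V), tolerance = 1e-6)
  # Wald machinery on a null cohort keeps alpha near zero
  co0 <- prepared_cohort(seed = 7, n = 250, alpha = 0,
                         baseline_hazard = 0.011471)
  fit0 <- fit_joint_model(co0, jm_spec(), se = TRUE)
  expect_lt(abs(fit0$alpha), 2.6 * fit0$se[["alpha"]])
})

test_that("finite-difference curvature is exact on a quadratic score", {
  # the same forward-differencing used for the Hessian, applied to an
  # analytic quadratic log-likelihood with known curvature
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  gr <- function(x) drop(A %*% x)   # gradient of 0.5 x'Ax
  H <- matrix(0, 2, 2)
  x0 <- c(0.3, -0.2)
  g0 <- gr(x0)
  for (j in 1:2) {
    h <- 1e-5 * max(1, abs(x0[j]))
    xj <- x0; xj[j] <- xj[j] + h
    H[, j] <- (gr(xj) - g0) / h
  }
  expect_equal((H + t(H)) / 2, A, tolerance = 1e-6)
})

test_that("hazard ratio report applies Wald arithmetic on the response scale", {
  fake <- structure(
    list(alpha = log(1.45), se = c(alpha = 0.167),
         spec = list(association_type = "current"),
         n_subjects = 1241L, n_events = 164L, converged = TRUE),
    class = "br_jm_fit")
  rep95 <- hazard_ratio_report(fake)
  expect_equal(round(rep95$hr, 2), 1.45)
  expect_equal(round(rep95$conf_low, 2), 1.05)
  expect_equal(round(rep95$conf_high, 2), 2.01)
  # alpha = 0: HR 1 with a log-symmetric interval
  fake0 <- fake; fake0$alpha <- 0
  rep0 <- hazard_ratio_report(fake0)
  expect_equal(rep0$hr, 1)
  expect_equal(rep0$conf_low * rep0$conf_high, 1, tolerance = 1e-12)
  # narrower level nests inside the wider one
  rep90 <- hazard_ratio_report(fake, level = 0.90)
  expect_gt(rep90$conf_low, rep95$conf_low)
  expect_lt(rep90$conf_high, rep95$conf_high)
})

test_that("diagnostics return residual tables of the right shape", {
  fit <- fit_joint_model(jm_test_cohort, jm_spec(), se = FALSE,
                         lmm_fit = jm_test_lmm)
  diag_out <- model_diagnostics(fit)
  expect_equal(nrow(diag_out$longitudinal), fit$n_obs)
  expect_equal(nrow(diag_out$survival), fit$n_subjects)
  # correctly specified simulation: mean martingale residual near zero
  mg <- diag_out$survival$martingale
  expect_lt(abs(mean(mg)), 3 * sd(mg) / sqrt(length(mg)))
  # noise-free cohort: longitudinal residuals vanish
  cfg0 <- sim_config(n_subjects = 40, sigma = 0, D = matrix(0, 3, 3),
                     seed = 3)
  co0 <- apply_eligibility(apply_censoring(generate_cohort(cfg0)))$cohort
  resp0 <- suppressMessages(compute_response(co0))
  fit0_lmm <- fit_lmm(resp0, basis = ncs_basis(c(0, 5), 1.25))
  resid0 <- resp0$response -
    drop(cbind(1, ncs_eval(fit0_lmm$basis, resp0$time_years),
               resp0$baseline_hba1c) %*% fit0_lmm$beta)
  expect_lt(max(abs(resid0)), 1e-6)
})

test_that("a cohort without events is rejected", {
  co <- jm_test_cohort
  co$events$event_indicator <- 0L
  expect_error(jm_prepare(co, jm_spec()), "at least one event")
})
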