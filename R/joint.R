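# Joint longitudinal-survival model with shared random effects:
# simultaneous ML estimation of the HbA1c response submodel and a
# proportional-hazards submodel whose log relative hazard involves the
# latent response -- its current value or its running integral.

#' Joint model specification
#'
#' Settings controlling the association structure and the numerical
#' scheme of [fit_joint_model()].
#'
#' @param association_type `"current"`: the hazard at t depends on the
#'   latent response m(t); `"cumulative"`: on its integral from 0 to t.
#' @param re_variant Random-effects structure of the longitudinal
#'   submodel; `"linear_re"` is the convergence fallback with a linear
#'   random time slope (fixed effects stay spline-based).
#' @param gh_points Gauss-Hermite nodes per random-effect dimension
#'   (odd, at least 5). Nodes are centered and scaled per subject at the
#'   empirical-Bayes posterior of the initial longitudinal fit
#'   (pseudo-adaptive quadrature), which keeps the node count modest.
#' @param hazard_quad_points Gauss-Legendre nodes for the cumulative
#'   hazard integral on (0, T_i) (at least 7).
#' @param baseline_hazard_knots Number of internal knots of the cubic
#'   B-spline for the log baseline hazard, placed at event-time
#'   quantiles.
#' @param se_method Standard-error method (numerical Hessian of the
#'   joint log-likelihood, obtained by differencing the analytic score).
#' @return An object of class `jm_spec`.
#' @export
jm_spec <- function(association_type = c("current", "cumulative"),
                    re_variant = c("spline_re", "linear_re"),
                    gh_points = 7L, hazard_quad_points = 15L,
                    baseline_hazard_knots = 5L,
                    se_method = "numerical_hessian") {
  association_type <- match.arg(association_type)
  re_variant <- match.arg(re_variant)
  gh_points <- as.integer(gh_points)
  hazard_quad_points <- as.integer(hazard_quad_points)
  if (gh_points < 5L || gh_points %% 2L == 0L) {
    stop("gh_points must be odd and at least 5", call. = FALSE)
  }
  if (hazard_quad_points < 7L) {
    stop("hazard_quad_points must be at least 7", call. = FALSE)
  }
  structure(list(association_type = association_type,
                 re_variant = re_variant, gh_points = gh_points,
                 hazard_quad_points = hazard_quad_points,
                 baseline_hazard_knots = as.integer(baseline_hazard_knots),
                 se_method = match.arg(se_method, "numerical_hessian")),
            class = "jm_spec")
}

# tensor-product Gauss-Hermite rule over d dimensions
gh_tensor <- function(gh_points, d) {
  gh <- pracma::gaussHermite(gh_points)
  grids <- rep(list(seq_len(gh_points)), d)
  idx <- as.matrix(expand.grid(grids))
  U <- matrix(gh$x[idx], nrow(idx), d)
  lw <- rowSums(matrix(log(gh$w[idx]), nrow(idx), d)) + rowSums(U^2)
  list(U = U, lw = lw)
}

#' Assemble the joint-model data object
#'
#' Prepares everything [fit_joint_model()] and [subject_loglik()] need:
#' per-subject longitudinal designs, survival quadrature designs, the
#' baseline-hazard B-spline (internal knots at event-time quantiles,
#' boundary at 0 and the longest follow-up), and the pseudo-adaptive
#' Gauss-Hermite nodes centered at each subject's empirical-Bayes
#' posterior from the initial longitudinal fit.
#'
#' @param cohort A prepared [br_cohort()] (censored, eligible subjects
#'   only).
#' @param spec A [jm_spec()].
#' @param lmm_fit Optional [fit_lmm()] result to reuse; fitted when
#'   `NULL`.
#' @return An object of class `br_jm_data`.
#' @export
jm_prepare <- function(cohort, spec = jm_spec(), lmm_fit = NULL) {
  stopifnot(inherits(cohort, "br_cohort"), inherits(spec, "jm_spec"))
  events <- dplyr::arrange(cohort$events, .data$subject_id)
  if (sum(events$event_indicator) < 1) {
    stop("joint model requires at least one event", call. = FALSE)
  }
  resp <- suppressMessages(compute_response(cohort))
  missing_ids <- setdiff(events$subject_id, unique(resp$subject_id))
  if (length(missing_ids)) {
    stop(length(missing_ids), " subject(s) lack response measurements; ",
         "run apply_eligibility() first", call. = FALSE)
  }
  if (is.null(lmm_fit)) {
    lmm_fit <- fit_lmm(resp, variant = spec$re_variant)
  }
  basis <- lmm_fit$basis
  d <- nrow(lmm_fit$D)
  eb <- empirical_bayes(lmm_fit)

  ev_times <- events$event_time_years[events$event_indicator == 1]
  tmax <- max(events$event_time_years)
  kint <- stats::quantile(
    ev_times, seq_len(spec$baseline_hazard_knots) /
      (spec$baseline_hazard_knots + 1), names = FALSE)
  kint <- unique(pmin(pmax(kint, 1e-6 * tmax), (1 - 1e-6) * tmax))
  sbasis <- bspline_basis(c(0, tmax), kint)

  ghr <- gh_tensor(spec$gh_points, d)
  gl <- gauss_legendre01(spec$hazard_quad_points)
  designs <- lmm_fit$designs
  ids <- vapply(designs, function(s) s$subject_id, numeric(1))
  stopifnot(setequal(ids, events$subject_id))
  ord <- match(events$subject_id, ids)

  ebm <- as.matrix(eb[, paste0("b", seq_len(d) - 1L)])
  eb_ids <- eb$subject_id

  subjects <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    s <- designs[[ord[k]]]
    Tk <- events$event_time_years[k]
    delta <- events$event_indicator[k]
    w <- s$w
    sq <- Tk * gl$x
    Wq <- Tk * gl$w
    Nq <- ncs_eval(basis, sq)
    NT <- ncs_eval(basis, Tk)
    if (spec$association_type == "current") {
      axT <- c(1, NT, w)
      Axq <- cbind(1, Nq, w)
      if (spec$re_variant == "spline_re") {
        azT <- c(1, NT); Azq <- cbind(1, Nq)
      } else {
        azT <- c(1, Tk); Azq <- cbind(1, sq)
      }
    } else {
      IT <- ncs_integral(basis, Tk)
      Iq <- ncs_integral(basis, sq)
      axT <- c(Tk, IT, w * Tk)
      Axq <- cbind(sq, Iq, w * sq)
      if (spec$re_variant == "spline_re") {
        azT <- c(Tk, IT); Azq <- cbind(sq, Iq)
      } else {
        azT <- c(Tk, Tk^2 / 2); Azq <- cbind(sq, sq^2 / 2)
      }
    }
    j <- match(events$subject_id[k], eb_ids)
    S <- eb$cond_cov[[j]] + diag(1e-10, d)
    Li <- t(chol(S))
    Bnodes <- matrix(ebm[j, ], nrow(ghr$U), d, byrow = TRUE) +
      sqrt(2) * ghr$U %*% t(Li)
    lw <- ghr$lw + 0.5 * d * log(2) + sum(log(diag(Li)))
    subjects[[k]] <- list(
      y = s$y, X = s$X, Z = s$Z, t = s$t,
      delta = as.numeric(delta), w = w,
      BT = drop(bspline_eval(sbasis, Tk)), axT = axT, azT = azT,
      Wq = Wq, Bq = bspline_eval(sbasis, sq), Axq = Axq, Azq = Azq,
      Bnodes = Bnodes, lw = lw
    )
  }
  provenance <- list(
    cohort_hash = rlang::hash(list(cohort$measurements, cohort$baseline,
                                   cohort$events)),
    sim_seed = if (!is.null(cohort$config)) cohort$config$seed
  )
  structure(
    list(subjects = subjects, subject_ids = events$subject_id,
         events = events, p = ncol(designs[[1]]$X), d = d,
         kb = sbasis$df, spec = spec, traj_basis = basis,
         surv_basis = sbasis, lmm_fit = lmm_fit, eb = eb,
         provenance = provenance),
    class = "br_jm_data"
  )
}

# pack a natural-scale parameter list into the working vector
jm_pack_params <- function(params, data) {
  L <- t(chol(params$D + diag(1e-12, nrow(params$D))))
  c(params$beta, L_to_theta(L), 0.5 * log(params$sigma2),
    params$gamma0, params$alpha, params$kappa)
}

jm_unpack_params <- function(par, data) {
  par <- unname(par)
  p <- data$p; d <- data$d; nth <- d * (d + 1) / 2
  L <- theta_to_L(par[p + seq_len(nth)], d)
  list(beta = par[seq_len(p)], D = L %*% t(L),
       sigma2 = exp(2 * par[p + nth + 1]),
       gamma0 = par[p + nth + 2], alpha = par[p + nth + 3],
       kappa = par[p + nth + 3 + seq_len(data$kb)])
}

# evaluate the joint log-likelihood (and score) at a working vector
jm_eval <- function(par, data, want_grad = FALSE) {
  cpp_jm_loglik(par, data$subjects, data$p, data$d, data$kb, want_grad)
}

#' Subject-level joint log-likelihood
#'
#' Evaluates log p(y_i, T_i, delta_i) for one subject at given
#' parameter values, integrating the shared random effects by the
#' pseudo-adaptive Gauss-Hermite rule held in `data`.
#'
#' @param data A [jm_prepare()] object.
#' @param params List with `beta`, `D`, `sigma2`, `gamma0`, `alpha`,
#'   `kappa` on the natural scale.
#' @param subject_id Subject identifier(s); default all.
#' @return Named numeric vector of per-subject log-likelihood values.
#' @export
subject_loglik <- function(data, params, subject_id = NULL) {
  stopifnot(inherits(data, "br_jm_data"))
  par <- jm_pack_params(params, data)
  res <- jm_eval(par, data)
  if (!is.finite(res$loglik)) {
    stop("non-finite joint log-likelihood at the supplied parameters",
         call. = FALSE)
  }
  lli <- drop(res$lli)
  names(lli) <- data$subject_ids
  if (is.null(subject_id)) lli else lli[as.character(subject_id)]
}

#' Log relative hazard contributed by the covariates
#'
#' The linear predictor of the survival submodel: gamma0 * baseline +
#' alpha * m(t) for the current-value association, or gamma0 * baseline
#' + alpha * integral of m over (0, t) for the cumulative association
#' (exact spline antiderivative).
#'
#' @param params List with `beta` (trajectory fixed effects), `gamma0`
#'   and `alpha`.
#' @param b Random-effect vector of the subject.
#' @param baseline_hba1c Baseline HbA1c (%).
#' @param t Times (years).
#' @param association_type `"current"` or `"cumulative"`.
#' @param basis The trajectory [ncs_basis()].
#' @param re_variant Random-effects structure matching `b`.
#' @return Numeric vector of log relative hazards at `t`.
#' @export
linear_predictor <- function(params, b, baseline_hba1c, t,
                             association_type = c("current", "cumulative"),
                             basis, re_variant = c("spline_re", "linear_re")) {
  association_type <- match.arg(association_type)
  re_variant <- match.arg(re_variant)
  if (association_type == "current") {
    N <- ncs_eval(basis, t)
    X <- cbind(1, N, baseline_hba1c)
    Z <- if (re_variant == "spline_re") cbind(1, N) else cbind(1, t)
  } else {
    I <- ncs_integral(basis, t)
    X <- cbind(t, I, baseline_hba1c * t)
    Z <- if (re_variant == "spline_re") cbind(t, I) else cbind(t, t^2 / 2)
  }
  drop(params$gamma0 * baseline_hba1c +
         params$alpha * (X %*% params$beta + Z %*% b))
}

#' Fit the joint longitudinal-survival model
#'
#' Two-stage initialization followed by direct quasi-Newton
#' maximization of the full joint log-likelihood. Stage one fits the
#' longitudinal mixed model by ML; stage two fits the survival
#' parameters (baseline-HbA1c coefficient, association, log baseline
#' hazard B-spline) with the longitudinal parameters held fixed; the
#' final stage maximizes over all parameters jointly. On non-convergence
#' with `spline_re` random effects the fit is automatically retried with
#' the `linear_re` fallback (recorded in the result).
#'
#' @param cohort A prepared [br_cohort()].
#' @param spec A [jm_spec()].
#' @param se Compute standard errors (inverse numerical Hessian) after
#'   fitting.
#' @param lmm_fit Optional initial longitudinal fit to reuse.
#' @return An object of class `br_jm_fit`.
#' @export
fit_joint_model <- function(cohort, spec = jm_spec(), se = TRUE,
                            lmm_fit = NULL) {
  fit <- jm_fit_once(cohort, spec, lmm_fit)
  if (!fit$converged && spec$re_variant == "spline_re") {
    spec2 <- spec
    spec2$re_variant <- "linear_re"
    fit2 <- jm_fit_once(cohort, spec2, NULL)
    if (fit2$converged) {
      fit2$fallback <- TRUE
      fit <- fit2
    }
  }
  if (se) fit <- standard_errors(fit)
  fit
}

jm_fit_once <- function(cohort, spec, lmm_fit) {
  data <- jm_prepare(cohort, spec, lmm_fit)
  lmm <- data$lmm_fit
  p <- data$p; d <- data$d; nth <- d * (d + 1) / 2; kb <- data$kb
  n_events <- sum(data$events$event_indicator)
  exposure <- sum(data$events$event_time_years)
  par0 <- c(lmm$beta, lmm$theta[seq_len(nth)], lmm$theta[nth + 1],
            0, 0, rep(log(n_events / exposure), kb))

  negfn <- function(par) {
    r <- jm_eval(par, data)
    if (!is.finite(r$loglik)) 1e10 else -r$loglik
  }
  neggr_env <- new.env(parent = emptyenv())
  neggr <- function(par) {
    if (!identical(par, neggr_env$par)) {
      neggr_env$res <- jm_eval(par, data, want_grad = TRUE)
      neggr_env$par <- par
    }
    r <- neggr_env$res
    if (!is.finite(r$loglik)) rep(0, length(par)) else -drop(r$grad)
  }

  # stage two: survival block only, longitudinal block fixed
  idx_surv <- (p + nth + 1) + seq_len(2 + kb)
  f2 <- function(sub) {
    par <- par0; par[idx_surv] <- sub
    negfn(par)
  }
  g2 <- function(sub) {
    par <- par0; par[idx_surv] <- sub
    neggr(par)[idx_surv]
  }
  o2 <- stats::optim(par0[idx_surv], f2, g2, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-9))
  par1 <- par0
  par1[idx_surv] <- o2$par
  stage_loglik <- -o2$value

  opt <- stats::optim(par1, negfn, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-11))
  res <- jm_eval(opt$par, data, want_grad = TRUE)
  converged <- opt$convergence == 0 && is.finite(res$loglik) &&
    max(abs(res$grad)) < 1e-4 * max(1, abs(res$loglik))
  est <- jm_unpack_params(opt$par, data)
  structure(
    list(beta = stats::setNames(est$beta, names(lmm$beta)),
         D = est$D, sigma2 = est$sigma2, gamma0 = est$gamma0,
         alpha = est$alpha, kappa = est$kappa,
         loglik = res$loglik, stage_loglik = stage_loglik,
         converged = converged, fallback = FALSE,
         n_subjects = length(data$subjects), n_events = n_events,
         n_obs = lmm$n_obs, par = opt$par, data = data,
         spec = data$spec, vcov = NULL, se = NULL),
    class = "br_jm_fit"
  )
}

#' @export
print.br_jm_fit <- function(x, ...) {
  cat(sprintf(
    "<br_jm_fit> %s association, %s, %d subjects / %d events, logLik %.2f%s%s\n",
    x$spec$association_type, x$spec$re_variant, x$n_subjects, x$n_events,
    x$loglik, if (x$converged) "" else " (NOT converged)",
    if (x$fallback) " [linear_re fallback]" else ""))
  cat(sprintf("  alpha (log HR per 1%% greater response%s): %.4f",
              if (x$spec$association_type == "cumulative") "-year" else "",
              x$alpha))
  if (!is.null(x$se)) cat(sprintf(" (SE %.4f)", x$se[["alpha"]]))
  cat(sprintf("\n  gamma0 (log HR per 1%% baseline HbA1c): %.4f\n",
              x$gamma0))
  invisible(x)
}

#' Standard errors for a fitted joint model
#'
#' Covariance of the parameter estimates as the inverse of the negative
#' Hessian of the joint log-likelihood at the optimum; the Hessian is
#' obtained by forward-differencing the analytic score. Variance
#' parameters live on the working (log-Cholesky, log-sigma) scale; the
#' residual-variance SE is mapped back by the delta method.
#'
#' @param fit A [fit_joint_model()] result.
#' @return The fit with `vcov` (working scale), `se` (named, natural
#'   scale for beta, gamma0, alpha, kappa and sigma2) and `wald`
#'   (z and p for alpha) filled in.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "br_jm_fit"))
  if (!fit$converged) {
    stop("fit did not converge; re-fit (or use the linear_re fallback) ",
         "before requesting standard errors", call. = FALSE)
  }
  data <- fit$data
  par <- fit$par
  np <- length(par)
  g0 <- -drop(jm_eval(par, data, want_grad = TRUE)$grad)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    h <- 1e-5 * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    gj <- -drop(jm_eval(pj, data, want_grad = TRUE)$grad)
    H[, j] <- (gj - g0) / h
  }
  H <- (H + t(H)) / 2   # Hessian of the negative log-likelihood
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
    stop("observed information is not positive definite; consider the ",
         "linear_re fallback variant", call. = FALSE)
  }
  p <- data$p; d <- data$d; nth <- d * (d + 1) / 2
  sed <- sqrt(diag(V))
  nm <- c(names(fit$beta), paste0("zeta", seq_len(nth)), "log_sigma",
          "gamma0", "alpha", paste0("kappa", seq_len(data$kb)))
  names(sed) <- nm
  sed[["log_sigma"]] <- NA  # replaced by delta-method sigma2 SE below
  se <- c(sed[seq_len(p)],
          sigma2 = unname(2 * fit$sigma2 * sqrt(V[p + nth + 1, p + nth + 1])),
          gamma0 = unname(sed[["gamma0"]]), alpha = unname(sed[["alpha"]]),
          sed[p + nth + 1 + 2 + seq_len(data$kb)])
  z <- fit$alpha / se[["alpha"]]
  fit$vcov <- V
  fit$vcov_names <- nm
  fit$se <- se
  fit$wald <- c(z = z, p = 2 * stats::pnorm(-abs(z)))
  fit
}

#' Hazard-ratio report for a fitted model
#'
#' Hazard ratio per 1% greater absolute HbA1c response (current value)
#' or per 1%-year greater cumulative response, with Wald confidence
#' interval and two-sided p-value.
#'
#' @param fit A fitted model (`br_jm_fit` or `br_cox_fit`).
#' @param level Confidence level.
#' @return One-row tibble: `model`, `term`, `hr`, `conf_low`,
#'   `conf_high`, `p`, `n`, `n_events`, `converged`.
#' @export
hazard_ratio_report <- function(fit, level = 0.95) {
  UseMethod("hazard_ratio_report")
}

# shared Wald HR arithmetic: exp(est), exp(est -/+ z se)
wald_hr_row <- function(model, term, est, se, level, n, n_events,
                        converged) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- est / se
  tibble::tibble(
    model = model, term = term, hr = exp(est),
    conf_low = exp(est - zq * se), conf_high = exp(est + zq * se),
    p = 2 * stats::pnorm(-abs(z)), n = n, n_events = n_events,
    converged = converged
  )
}

#' @export
hazard_ratio_report.br_jm_fit <- function(fit, level = 0.95) {
  if (is.null(fit$se)) fit <- standard_errors(fit)
  model <- if (fit$spec$association_type == "current") "jmcv" else "jmcum"
  wald_hr_row(model, "response", fit$alpha, fit$se[["alpha"]], level,
              fit$n_subjects, fit$n_events, fit$converged)
}

#' Serialize a fitted joint model to a structured text document
#'
#' Writes every estimated parameter block, the standard errors and
#' working-scale covariance (when computed), the specification, and the
#' provenance of the underlying cohort (content hash, simulation seed
#' if any) as YAML.
#'
#' @param fit A [fit_joint_model()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "br_jm_fit"))
  doc <- list(
    model = if (fit$spec$association_type == "current") "jmcv" else "jmcum",
    spec = unclass(fit$spec),
    estimates = list(
      beta = as.list(fit$beta),
      D = apply(fit$D, 1, as.numeric, simplify = FALSE),
      sigma2 = fit$sigma2, gamma0 = fit$gamma0, alpha = fit$alpha,
      kappa = as.numeric(fit$kappa)
    ),
    se = if (!is.null(fit$se)) as.list(fit$se),
    vcov_working = if (!is.null(fit$vcov)) {
      apply(fit$vcov, 1, as.numeric, simplify = FALSE)
    },
    vcov_names = fit$vcov_names,
    loglik = fit$loglik, converged = fit$converged,
    fallback = fit$fallback,
    n_subjects = fit$n_subjects, n_events = fit$n_events,
    baseline_hazard_knots = list(
      boundary = fit$data$surv_basis$boundary_knots,
      internal = fit$data$surv_basis$internal_knots),
    trajectory_knots = list(
      boundary = fit$data$traj_basis$boundary_knots,
      internal = fit$data$traj_basis$internal_knots),
    provenance = fit$data$provenance
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Residual diagnostics for a fitted joint model
#'
#' Exports standardized longitudinal residuals (observed minus fitted
#' subject-specific trajectory, scaled by the residual SD) and
#' martingale-type survival residuals (event indicator minus fitted
#' cumulative hazard at the subject's follow-up end), both computed at
#' the empirical-Bayes random-effect estimates under the fitted
#' parameters.
#'
#' @param fit A [fit_joint_model()] result.
#' @return List of two tibbles: `longitudinal` (one row per
#'   measurement) and `survival` (one row per subject).
#' @export
model_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "br_jm_fit"))
  data <- fit$data
  sig <- sqrt(fit$sigma2)
  lres <- vector("list", length(data$subjects))
  sres <- numeric(length(data$subjects))
  for (k in seq_along(data$subjects)) {
    s <- data$subjects[[k]]
    V <- s$Z %*% fit$D %*% t(s$Z) + diag(fit$sigma2, length(s$y))
    r <- s$y - drop(s$X %*% fit$beta)
    bhat <- drop(fit$D %*% t(s$Z) %*% solve(V, r))
    resid <- (r - drop(s$Z %*% bhat)) / sig
    lres[[k]] <- tibble::tibble(
      subject_id = data$subject_ids[k],
      time_years = s$t, resid_std = resid)
    eta_q <- drop(s$Bq %*% fit$kappa) + fit$gamma0 * s$w +
      fit$alpha * drop(s$Axq %*% fit$beta + s$Azq %*% bhat)
    sres[k] <- s$delta - sum(s$Wq * exp(eta_q))
  }
  list(
    longitudinal = dplyr::bind_rows(lres),
    survival = tibble::tibble(subject_id = data$subject_ids,
                              martingale = sres)
  )
}
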