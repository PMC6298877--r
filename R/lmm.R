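# Longitudinal submodel: linear mixed model for HbA1c response with
# natural-cubic-spline fixed and random time effects and a baseline
# HbA1c fixed effect, fitted by maximum likelihood (ML, not REML, so the
# standalone fit is on the same likelihood scale as the joint model and
# is a valid initializer for it).

# per-subject design matrices; resp is a compute_response() tibble
lmm_designs <- function(resp, basis, variant) {
  split_idx <- split(seq_len(nrow(resp)), resp$subject_id)
  lapply(split_idx, function(ix) {
    t_i <- resp$time_years[ix]
    w_i <- resp$baseline_hba1c[ix][1]
    N <- ncs_eval(basis, t_i)
    X <- cbind(1, N, w_i)
    colnames(X) <- c("(Intercept)", "ncs1", "ncs2", "baseline_hba1c")
    Z <- if (variant == "spline_re") cbind(1, N) else cbind(1, t_i)
    list(subject_id = resp$subject_id[ix][1], y = resp$response[ix],
         t = t_i, w = w_i, X = X, Z = Z)
  })
}

# lower-triangular Cholesky factor from log-diagonal parameterization
theta_to_L <- function(theta, d) {
  L <- matrix(0, d, d)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

L_to_theta <- function(L) {
  d <- nrow(L)
  M <- L
  diag(M) <- log(pmax(diag(L), 1e-10))
  M[lower.tri(M, diag = TRUE)]
}

# group subjects sharing a visit-time pattern so V and its inverse are
# computed once per pattern during optimization
lmm_pattern_groups <- function(designs) {
  pattern <- vapply(designs, function(s) paste(signif(s$t, 12),
                                               collapse = ","), "")
  lapply(split(seq_along(designs), pattern), function(g) {
    s1 <- designs[[g[1]]]
    n_i <- length(s1$y)
    list(Z = s1$Z,
         X0 = s1$X[, -ncol(s1$X), drop = FALSE],
         Y = matrix(vapply(g, function(i) designs[[i]]$y, numeric(n_i)),
                    n_i),
         ws = vapply(g, function(i) designs[[i]]$w, numeric(1)),
         n_i = n_i, m = length(g))
  })
}

# Profiled ML negative log-likelihood over the variance parameters,
# with analytic gradient. beta is profiled out by GLS; by the envelope
# theorem the gradient at the profiled beta needs no d(beta)/d(theta)
# term. Returns list(nll, grad, details).
lmm_profile_nll <- function(theta, groups, d, p) {
  nth <- d * (d + 1) / 2
  L <- theta_to_L(theta[seq_len(nth)], d)
  D <- L %*% t(L)
  sigma2 <- exp(2 * theta[nth + 1])
  A <- matrix(0, p, p); cvec <- numeric(p)
  yPy <- 0; logdet <- 0; N <- 0
  cache <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gr <- groups[[k]]
    V <- gr$Z %*% D %*% t(gr$Z) + diag(sigma2, gr$n_i)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    P <- chol2inv(U)
    one <- rep(1, gr$n_i)
    PX0 <- P %*% gr$X0; P1 <- P %*% one
    PY <- P %*% gr$Y
    j <- seq_len(p - 1)
    A[j, j] <- A[j, j] + gr$m * crossprod(gr$X0, PX0)
    A[j, p] <- A[j, p] + drop(crossprod(gr$X0, P1)) * sum(gr$ws)
    A[p, j] <- A[j, p]
    A[p, p] <- A[p, p] + sum(one * P1) * sum(gr$ws^2)
    cvec[j] <- cvec[j] + drop(crossprod(gr$X0, rowSums(PY)))
    cvec[p] <- cvec[p] + sum(gr$ws * colSums(PY))
    yPy <- yPy + sum(gr$Y * PY)
    logdet <- logdet + gr$m * 2 * sum(log(diag(U)))
    N <- N + gr$m * gr$n_i
    cache[[k]] <- list(P = P, PX0 = PX0, P1 = P1, PY = PY)
  }
  beta <- tryCatch(solve(A, cvec), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  quad <- yPy - sum(beta * cvec)
  ll <- -0.5 * (N * log(2 * pi) + logdet + quad)
  if (!is.finite(ll)) return(NULL)

  # gradient: dl/dV terms via M = sum_g (m_g W_g - sum_i v_i v_i'),
  # W = Z'PZ, v_i = Z'P r_i, plus the residual sigma^2 direction
  Mtot <- matrix(0, d, d)
  tr_term <- 0; uu_term <- 0
  for (k in seq_along(groups)) {
    gr <- groups[[k]]; ch <- cache[[k]]
    j <- seq_len(p - 1)
    # P r_i for all subjects in the group, reusing cached products
    Umat <- ch$PY - ch$PX0 %*% matrix(beta[j], ncol = 1) %*%
      rep(1, gr$m) - ch$P1 %*% t(gr$ws * beta[p])
    v <- crossprod(gr$Z, Umat)                      # d x m
    W <- crossprod(gr$Z, ch$P %*% gr$Z)             # d x d
    Mtot <- Mtot + gr$m * W - tcrossprod(v)
    tr_term <- tr_term + gr$m * sum(diag(ch$P))
    uu_term <- uu_term + sum(Umat^2)
  }
  GL <- -(Mtot %*% L)        # d nll/d L_{ab} = +(M L)_{ab}; nll = -ll
  gmatrix <- -GL             # gradient of nll w.r.t. L entries
  diag(gmatrix) <- diag(gmatrix) * diag(L)  # chain rule for log-diagonal
  gtheta <- gmatrix[lower.tri(gmatrix, diag = TRUE)]
  gsigma <- 0.5 * (tr_term - uu_term) * 2 * sigma2  # wrt log sigma
  list(nll = -ll, grad = c(gtheta, gsigma),
       details = list(loglik = ll, beta = beta, D = D, sigma2 = sigma2))
}

# default trajectory knots: left boundary at randomization, right at the
# last observed time, internal knot at the pooled median observed time
default_traj_basis <- function(times) {
  bmax <- max(times)
  knot <- stats::median(times)
  if (knot <= 0 || knot >= bmax) knot <- bmax / 2
  ncs_basis(c(0, bmax), knot)
}

#' Fit the longitudinal HbA1c response submodel
#'
#' Maximum-likelihood linear mixed model for the response series:
#' fixed effects are an intercept, two natural-cubic-spline time terms
#' (one internal knot at the pooled median observed measurement time)
#' and baseline HbA1c; random effects are the subject-specific intercept
#' and spline terms (`spline_re`) or intercept and linear time slope
#' (`linear_re`, the convergence fallback). The random-effects
#' covariance is optimized on a log-Cholesky parameterization, which
#' enforces positive semi-definiteness.
#'
#' @param resp Response tibble from [compute_response()].
#' @param variant `"spline_re"` (default) or `"linear_re"`.
#' @param basis Optional [ncs_basis()] for time; computed from the data
#'   when `NULL`.
#' @return An object of class `br_lmm_fit` with elements `beta`, `D`,
#'   `sigma2`, `loglik`, `converged`, `n_subjects`, `n_obs`, `basis`,
#'   `variant`, plus working internals used by the joint model.
#' @export
fit_lmm <- function(resp, variant = c("spline_re", "linear_re"),
                    basis = NULL) {
  variant <- match.arg(variant)
  stopifnot(all(c("subject_id", "time_years", "response",
                  "baseline_hba1c") %in% names(resp)))
  if (is.null(basis)) basis <- default_traj_basis(resp$time_years)
  designs <- lmm_designs(resp, basis, variant)
  n_multi <- sum(vapply(designs, function(s) length(s$y) > 1, TRUE))
  if (n_multi == 0) {
    stop("all subjects have a single measurement; random-effects ",
         "covariance is not identifiable", call. = FALSE)
  }
  d <- if (variant == "spline_re") 3L else 2L
  nth <- d * (d + 1) / 2
  p <- ncol(designs[[1]]$X)
  groups <- lmm_pattern_groups(designs)
  sd0 <- stats::sd(resp$response)
  start <- c(L_to_theta(diag(rep(max(sd0 / 2, 0.05), d))),
             log(max(sd0 / 2, 0.05)))
  last <- new.env(parent = emptyenv())
  evalf <- function(th) {
    if (!identical(th, last$th)) {
      last$res <- lmm_profile_nll(th, groups, d, p)
      last$th <- th
    }
    last$res
  }
  obj <- function(th) {
    r <- evalf(th)
    if (is.null(r)) 1e10 else r$nll
  }
  gfun <- function(th) {
    r <- evalf(th)
    if (is.null(r)) rep(0, length(th)) else r$grad
  }
  # bounds keep log-scale parameters away from degeneracy
  lower <- rep(-Inf, nth + 1); upper <- rep(Inf, nth + 1)
  idx <- matrix(0L, d, d)
  idx[lower.tri(idx, diag = TRUE)] <- seq_len(nth)
  lower[c(diag(idx), nth + 1)] <- -12
  ctl <- list(iter.max = 500, eval.max = 1000, rel.tol = 1e-12)
  opt <- stats::nlminb(start, obj, gradient = gfun, lower = lower,
                       upper = upper, control = ctl)
  if (opt$convergence != 0 || !is.finite(opt$objective)) {
    jitter <- 0.2 * sin(7 * seq_along(start))  # deterministic restart
    opt2 <- stats::nlminb(start + jitter, obj, gradient = gfun,
                          lower = lower, upper = upper, control = ctl)
    if (is.finite(opt2$objective) && opt2$objective < opt$objective) {
      opt <- opt2
    }
  }
  res <- evalf(opt$par)
  if (is.null(res)) stop("longitudinal model fit failed", call. = FALSE)
  det <- res$details
  converged <- is.finite(det$loglik) &&
    max(abs(res$grad)) < 1e-4 * max(1, abs(det$loglik))
  names(det$beta) <- colnames(designs[[1]]$X)
  structure(
    list(beta = det$beta, D = det$D, sigma2 = det$sigma2,
         loglik = det$loglik, converged = converged,
         n_subjects = length(designs), n_obs = nrow(resp),
         basis = basis, variant = variant,
         theta = opt$par, designs = designs, resp = resp),
    class = "br_lmm_fit"
  )
}

#' @export
print.br_lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<br_lmm_fit> %s, %d subjects / %d obs, logLik %.2f%s\n",
    x$variant, x$n_subjects, x$n_obs, x$loglik,
    if (x$converged) "" else " (NOT converged)"))
  print(round(x$beta, 4))
  invisible(x)
}

#' Log-likelihood of the longitudinal model at given parameters
#'
#' Evaluates the marginal Gaussian log-likelihood of a response data set
#' at supplied parameter values (not necessarily the ML estimates) —
#' used to check the joint likelihood against its longitudinal factor.
#'
#' @inheritParams fit_lmm
#' @param beta Fixed effects (intercept, spline terms, baseline).
#' @param D Random-effects covariance.
#' @param sigma2 Residual variance.
#' @return Scalar log-likelihood.
#' @export
lmm_loglik <- function(resp, basis, beta, D, sigma2,
                       variant = c("spline_re", "linear_re")) {
  variant <- match.arg(variant)
  designs <- lmm_designs(resp, basis, variant)
  ll <- 0
  for (s in designs) {
    V <- s$Z %*% D %*% t(s$Z) + diag(sigma2, length(s$y))
    r <- s$y - drop(s$X %*% beta)
    U <- chol(V)
    z <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (length(s$y) * log(2 * pi) + 2 * sum(log(diag(U))) +
                        sum(z^2))
  }
  ll
}

#' Empirical Bayes random-effect estimates
#'
#' Closed-form posterior mean and covariance of each subject's random
#' effects under the fitted Gaussian model (mean and mode coincide).
#' The formulation b = D Z' V^-1 (y - X beta) remains valid when D is
#' singular, including the degenerate D = 0 case.
#'
#' @param fit A [fit_lmm()] result.
#' @return Tibble with `subject_id`, one `b*` column per random effect,
#'   and a `cond_cov` list-column with the conditional covariance.
#' @export
empirical_bayes <- function(fit) {
  stopifnot(inherits(fit, "br_lmm_fit"))
  d <- nrow(fit$D)
  out <- lapply(fit$designs, function(s) {
    V <- s$Z %*% fit$D %*% t(s$Z) + diag(fit$sigma2, length(s$y))
    r <- s$y - drop(s$X %*% fit$beta)
    DZt <- fit$D %*% t(s$Z)
    Vi <- chol2inv(chol(V))
    b <- drop(DZt %*% Vi %*% r)
    S <- fit$D - DZt %*% Vi %*% t(DZt)
    list(id = s$subject_id, b = b, S = (S + t(S)) / 2)
  })
  res <- tibble::tibble(
    subject_id = vapply(out, function(o) o$id, numeric(1))
  )
  bm <- t(vapply(out, function(o) o$b, numeric(d)))
  colnames(bm) <- paste0("b", seq_len(d) - 1L)
  res <- dplyr::bind_cols(res, tibble::as_tibble(bm))
  res$cond_cov <- lapply(out, function(o) o$S)
  res
}

#' Predict a subject's latent response trajectory
#'
#' Deterministic evaluation of the fitted mean trajectory plus supplied
#' subject effects on a time grid, on the same (response-positive) scale
#' as the fitted data. At t = 0 the spline terms vanish (anchoring), so
#' the value is the intercept, baseline effect and random intercept.
#'
#' @param fit A [fit_lmm()] result.
#' @param baseline_hba1c Baseline HbA1c (%).
#' @param t Time grid (years).
#' @param b Random-effect vector (defaults to the population average 0).
#' @return Tibble with `time_years` and `response`.
#' @export
predict_trajectory <- function(fit, baseline_hba1c, t,
                               b = rep(0, nrow(fit$D))) {
  stopifnot(inherits(fit, "br_lmm_fit"), length(b) == nrow(fit$D))
  N <- ncs_eval(fit$basis, t)
  X <- cbind(1, N, baseline_hba1c)
  Z <- if (fit$variant == "spline_re") cbind(1, N) else cbind(1, t)
  tibble::tibble(time_years = t,
                 response = drop(X %*% fit$beta + Z %*% b))
}
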