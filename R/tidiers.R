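# broom-style tidiers for the three fitted-model classes

#' @export
tidy.br_lmm_fit <- function(x, ...) {
  vc <- x$D[lower.tri(x$D, diag = TRUE)]
  d <- nrow(x$D)
  nm <- outer(seq_len(d) - 1L, seq_len(d) - 1L,
              function(i, j) paste0("D[b", i, ",b", j, "]"))
  tibble::tibble(
    term = c(names(x$beta), nm[lower.tri(nm, diag = TRUE)], "sigma2"),
    estimate = c(unname(x$beta), vc, x$sigma2),
    type = c(rep("fixed", length(x$beta)),
             rep("var_cov", length(vc)), "residual")
  )
}

#' @export
glance.br_lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma2 = x$sigma2,
                 n_subjects = x$n_subjects, n_obs = x$n_obs,
                 variant = x$variant, converged = x$converged)
}

#' @export
tidy.br_jm_fit <- function(x, ...) {
  est <- c(unname(x$beta), x$gamma0, x$alpha)
  term <- c(names(x$beta), "gamma0", "alpha")
  se <- rep(NA_real_, length(est))
  if (!is.null(x$se)) {
    se <- c(unname(x$se[seq_along(x$beta)]), x$se[["gamma0"]],
            x$se[["alpha"]])
  }
  z <- est / se
  tibble::tibble(term = term, estimate = est, std.error = se,
                 statistic = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' @export
glance.br_jm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_subjects = x$n_subjects,
                 n_events = x$n_events,
                 association = x$spec$association_type,
                 re_variant = x$spec$re_variant,
                 fallback = x$fallback, converged = x$converged)
}

#' @export
tidy.br_cox_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' @export
glance.br_cox_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_subjects = x$n,
                 n_events = x$n_events, model = x$model,
                 ties = x$ties_method, converged = x$converged)
}
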