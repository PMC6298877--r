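# shared fixtures, all generated in code

# small prepared cohort for estimator tests
prepared_cohort <- function(seed = 42, n = 300, alpha = 0.35,
                            sigma = 0.35,
                            association_type = "current",
                            baseline_hazard = NULL, ...) {
  if (is.null(baseline_hazard)) {
    baseline_hazard <- if (association_type == "current") 0.018871
    else 0.018716
  }
  cfg <- sim_config(n_subjects = n, alpha = alpha, sigma = sigma,
                    association_type = association_type,
                    baseline_hazard = baseline_hazard, seed = seed, ...)
  apply_eligibility(apply_censoring(generate_cohort(cfg)))$cohort
}

# hand-built three-subject cohort with known times for prep tests
toy_cohort <- function() {
  measurements <- tibble::tibble(
    subject_id = c(1L, 1L, 2L, 3L, 3L, 3L),
    time_years = c(0.5, 1.0, 0.5, 0.25, 0.75, 1.5),
    hba1c_pct = c(6.8, 6.9, 7.0, 6.5, 6.6, 6.4)
  )
  baseline <- tibble::tibble(
    subject_id = 1:3, arm = "drug",
    baseline_hba1c_pct = c(7.3, 7.5, 7.0),
    pre_trial_history = c(FALSE, TRUE, FALSE)
  )
  events <- tibble::tibble(
    subject_id = 1:3,
    event_time_years = c(2.0, 1.2, 1.8),
    event_indicator = c(1L, 0L, 1L),
    severity = c("mild", NA, "severe")
  )
  br_cohort(measurements, baseline, events)
}

# independent Cox partial log-likelihood by exhaustive risk-set
# enumeration on counting-process data (Breslow ties)
brute_force_cox_loglik <- function(cp, beta) {
  lp <- as.matrix(cp[, c("response_at_start", "baseline_hba1c")]) %*% beta
  ev <- which(cp$event_in_interval == 1)
  ll <- 0
  for (j in ev) {
    tj <- cp$stop[j]
    risk <- cp$start < tj & tj <= cp$stop
    ll <- ll + lp[j] - log(sum(exp(lp[risk])))
  }
  ll
}

# dense tensor-grid brute-force marginal log-likelihood of one subject:
# E_{b ~ N(0, D)} [ p(y | b) p(T, delta | b) ] by non-adaptive
# Gauss-Hermite with nodes_per_dim nodes in each dimension
brute_force_subject_loglik <- function(s, params, d, nodes_per_dim = 200,
                                       chunk = 2e5) {
  gh <- pracma::gaussHermite(nodes_per_dim)
  L <- t(chol(params$D))
  idx <- as.matrix(expand.grid(rep(list(seq_len(nodes_per_dim)), d)))
  total_max <- -Inf
  # two passes: find max then accumulate, to keep logsumexp stable
  pass <- function() {
    out <- numeric(0)
    for (start in seq(1, nrow(idx), by = chunk)) {
      rows <- start:min(start + chunk - 1, nrow(idx))
      U <- matrix(gh$x[idx[rows, ]], length(rows), d)
      lw <- rowSums(matrix(log(gh$w[idx[rows, ]]), length(rows), d))
      B <- sqrt(2) * U %*% t(L)
      r <- s$y - drop(s$X %*% params$beta)
      E <- matrix(r, length(r), length(rows)) - s$Z %*% t(B)
      ll_y <- -0.5 * length(s$y) * log(2 * pi * params$sigma2) -
        colSums(E^2) / (2 * params$sigma2)
      lhT <- drop(s$BT %*% params$kappa) + params$gamma0 * s$w +
        params$alpha * (drop(s$axT %*% params$beta) + drop(B %*% s$azT))
      eta <- matrix(drop(s$Bq %*% params$kappa) + params$gamma0 * s$w +
                      params$alpha * drop(s$Axq %*% params$beta),
                    length(s$Wq), length(rows)) +
        params$alpha * (s$Azq %*% t(B))
      H <- drop(t(exp(eta)) %*% s$Wq)
      ll_T <- s$delta * lhT - H
      out <- c(out, lw + ll_y + ll_T)
    }
    out
  }
  g <- pass()
  m <- max(g)
  m + log(sum(exp(g - m))) - 0.5 * d * log(pi)
}
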