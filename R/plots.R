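# ggplot2 visualizations of cohorts, fits and hazard-ratio reports

#' Plot observed HbA1c response trajectories
#'
#' Spaghetti plot of observed response series (response-positive
#' convention) for a sample of subjects, colored by event status.
#'
#' @param object A [br_cohort()].
#' @param n_sample Number of subjects to draw (all if fewer).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_cohort <- function(object, n_sample = 60, ...) {
  resp <- suppressMessages(compute_response(object))
  ids <- unique(resp$subject_id)
  if (length(ids) > n_sample) ids <- ids[seq_len(n_sample)]
  df <- resp |>
    dplyr::filter(.data$subject_id %in% ids) |>
    dplyr::inner_join(
      dplyr::select(object$events, "subject_id",
                    event = "event_indicator"),
      by = "subject_id"
    ) |>
    dplyr::mutate(status = ifelse(.data$event == 1, "event", "censored"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$response,
                                   group = .data$subject_id,
                                   color = .data$status)) +
    ggplot2::geom_line(alpha = 0.45) +
    ggplot2::labs(x = "Years since randomization",
                  y = "HbA1c response (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fitted mean response trajectory
#'
#' Population-average latent response curve at a reference baseline
#' HbA1c, with the observed measurements as background.
#'
#' @param object A [fit_lmm()] result.
#' @param baseline_hba1c Reference baseline HbA1c (%).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.br_lmm_fit <- function(object, baseline_hba1c = 7.3, ...) {
  grid <- seq(0, max(object$resp$time_years), length.out = 101)
  mu <- predict_trajectory(object, baseline_hba1c, grid)
  ggplot2::ggplot(object$resp,
                  ggplot2::aes(.data$time_years, .data$response)) +
    ggplot2::geom_point(alpha = 0.08, size = 0.5) +
    ggplot2::geom_line(data = mu, ggplot2::aes(.data$time_years,
                                               .data$response),
                       color = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "Years since randomization",
                  y = "HbA1c response (%)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted joint model
#'
#' Shows the estimated population-average latent response trajectory
#' together with the estimated baseline hazard function.
#'
#' @param object A [fit_joint_model()] result.
#' @param baseline_hba1c Reference baseline HbA1c (%).
#' @param ... Unused.
#' @return A ggplot object (hazard scaled to the trajectory panel).
#' @export
autoplot.br_jm_fit <- function(object, baseline_hba1c = 7.3, ...) {
  tmax <- max(object$data$events$event_time_years)
  grid <- seq(0.01, tmax, length.out = 151)
  N <- ncs_eval(object$data$traj_basis, grid)
  mu <- drop(cbind(1, N, baseline_hba1c) %*% object$beta)
  h0 <- exp(drop(bspline_eval(object$data$surv_basis, grid) %*%
                   object$kappa))
  df <- tibble::tibble(
    time = rep(grid, 2),
    value = c(mu, h0),
    what = rep(c("Mean latent response (%)",
                 "Baseline hazard (events/year)"), each = length(grid))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Years since randomization", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard-ratio report rows
#'
#' @param report Tibble of [hazard_ratio_report()] rows (optionally with
#'   a `scenario` column from [run_specificity_grid()]).
#' @return A ggplot object on the log-HR scale.
#' @export
plot_hr_forest <- function(report) {
  stopifnot(all(c("model", "hr", "conf_low", "conf_high") %in%
                  names(report)))
  report$label <- if ("scenario" %in% names(report)) {
    paste(report$scenario, report$model, sep = " / ")
  } else {
    report$model
  }
  ggplot2::ggplot(report, ggplot2::aes(.data$hr, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HR per 1% greater HbA1c response", y = NULL) +
    ggplot2::theme_minimal()
}
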