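# Cohort preparation: response definition, eligibility, censoring, and
# the two derived analysis tables (counting-process and landmark).

#' Compute the HbA1c response series
#'
#' Joins the measurement and baseline tables and computes the response
#' at each retained visit. Two sign conventions are supported:
#' `"response_positive"` (the package default, response = baseline minus
#' current HbA1c, so a fall in glucose is a positive response — hazard
#' ratios downstream are then per 1% *greater* response) and
#' `"change_from_baseline"` (visit minus baseline, the raw change).
#'
#' @param cohort A [br_cohort()].
#' @param convention Sign convention, see above.
#' @return Tibble with columns `subject_id`, `time_years`, `response`,
#'   `baseline_hba1c`. Subjects with no post-baseline measurements are
#'   absent (flagged with a message, not an error).
#' @export
compute_response <- function(cohort,
                             convention = c("response_positive",
                                            "change_from_baseline")) {
  stopifnot(inherits(cohort, "br_cohort"))
  convention <- match.arg(convention)
  sgn <- if (convention == "response_positive") -1 else 1
  out <- cohort$measurements |>
    dplyr::filter(.data$time_years > 0) |>
    dplyr::inner_join(
      dplyr::select(cohort$baseline, "subject_id",
                    baseline_hba1c = "baseline_hba1c_pct"),
      by = "subject_id"
    ) |>
    dplyr::mutate(response = sgn * (.data$hba1c_pct - .data$baseline_hba1c)) |>
    dplyr::select("subject_id", "time_years", "response", "baseline_hba1c") |>
    dplyr::arrange(.data$subject_id, .data$time_years)
  n_empty <- sum(!cohort$baseline$subject_id %in% out$subject_id)
  if (n_empty > 0) {
    rlang::inform(sprintf(
      "%d subject(s) have no post-baseline measurements", n_empty))
  }
  out
}

#' Apply eligibility rules and the severity sensitivity filter
#'
#' Implements the analysis eligibility rules: every subject must have at
#' least one HbA1c measurement strictly before their event (or
#' censoring) time; for side effects with a recorded pre-trial history
#' flag (edema), flagged subjects are excluded; and under a severity
#' sensitivity filter, events below the qualifying grade are downgraded
#' to censoring at the event time (follow-up is not extended past the
#' first any-grade event).
#'
#' @param cohort A [br_cohort()].
#' @param side_effect_label Label of the side effect under analysis;
#'   `"edema"` triggers the pre-trial-history exclusion.
#' @param severity_filter One of `"all"`, `"moderate_plus"`, `"severe"`.
#' @return List with `cohort` (filtered [br_cohort()]), `exclusions`
#'   (tibble of reason/n; their sum plus the retained count equals the
#'   input count) and `n_downgraded` (events recoded as censored).
#' @export
apply_eligibility <- function(cohort, side_effect_label = "event",
                              severity_filter = c("all", "moderate_plus",
                                                  "severe")) {
  stopifnot(inherits(cohort, "br_cohort"))
  severity_filter <- match.arg(severity_filter)
  events <- cohort$events
  baseline <- cohort$baseline
  n_in <- nrow(baseline)

  # 1) pre-trial history exclusion (side effects with a history flag)
  excl_hist <- integer(0)
  if (identical(side_effect_label, "edema")) {
    excl_hist <- baseline$subject_id[baseline$pre_trial_history]
  }

  # 2) severity downgrade: non-qualifying events become censoring at the
  #    event time (conservative: follow-up is not extended)
  keep_sev <- switch(severity_filter,
                     all = c("mild", "moderate", "severe"),
                     moderate_plus = c("moderate", "severe"),
                     severe = "severe")
  bad <- !is.na(events$severity) & !(events$severity %in%
                                       c("mild", "moderate", "severe"))
  if (any(bad)) {
    stop("unknown severity label(s): ",
         paste(unique(events$severity[bad]), collapse = ", "), call. = FALSE)
  }
  downgrade <- events$event_indicator == 1 &
    !(events$severity %in% keep_sev)
  n_downgraded <- sum(downgrade)
  events$event_indicator[downgrade] <- 0
  events$severity[downgrade] <- NA_character_

  # 3) at least one measurement strictly before the event/censoring time
  first_meas <- cohort$measurements |>
    dplyr::filter(.data$time_years > 0) |>
    dplyr::summarise(first_time = min(.data$time_years),
                     .by = "subject_id")
  ev_first <- dplyr::left_join(events, first_meas, by = "subject_id")
  no_pre <- ev_first$subject_id[is.na(ev_first$first_time) |
                                  ev_first$first_time >=
                                    ev_first$event_time_years]
  no_pre <- setdiff(no_pre, excl_hist)

  drop_ids <- union(excl_hist, no_pre)
  keep <- !baseline$subject_id %in% drop_ids
  out <- br_cohort(
    dplyr::filter(cohort$measurements, !.data$subject_id %in% drop_ids),
    baseline[keep, , drop = FALSE],
    dplyr::filter(events, !.data$subject_id %in% drop_ids),
    config = cohort$config
  )
  exclusions <- tibble::tibble(
    reason = c("pre_trial_history", "no_pre_event_measure"),
    n = c(length(excl_hist), length(no_pre))
  )
  stopifnot(sum(exclusions$n) + nrow(out$baseline) == n_in)
  list(cohort = out, exclusions = exclusions, n_downgraded = n_downgraded)
}

#' Apply administrative censoring
#'
#' Event or censoring times beyond the administrative horizon are
#' truncated to it (with the event indicator cleared), and measurements
#' after each subject's effective follow-up end are dropped, so the
#' longitudinal record stops at the event/censoring time.
#'
#' @param cohort A [br_cohort()].
#' @param admin_time Administrative horizon in years.
#' @return A [br_cohort()].
#' @export
apply_censoring <- function(cohort, admin_time = 5) {
  stopifnot(inherits(cohort, "br_cohort"), admin_time > 0)
  events <- cohort$events
  over <- events$event_time_years > admin_time
  events$event_time_years[over] <- admin_time
  events$event_indicator[over] <- 0
  events$severity[over] <- NA_character_
  meas <- cohort$measurements |>
    dplyr::inner_join(
      dplyr::select(events, "subject_id", end = "event_time_years"),
      by = "subject_id"
    ) |>
    dplyr::filter(.data$time_years <= .data$end) |>
    dplyr::select(-"end")
  br_cohort(meas, cohort$baseline, events, config = cohort$config)
}

#' Expand a cohort into counting-process (start, stop] intervals
#'
#' Builds the start/stop interval table for the time-dependent Cox
#' comparator: interval j runs from measurement time t_j to the next
#' measurement (or the follow-up end), carrying the response observed at
#' t_j — exact last-observation-carried-forward semantics. Subjects
#' enter the risk set at their first measurement.
#'
#' @param cohort A [br_cohort()] (already censored/filtered).
#' @param convention Sign convention passed to [compute_response()].
#' @return Tibble with columns `subject_id`, `start`, `stop`,
#'   `event_in_interval`, `response_at_start`, `baseline_hba1c`. Per
#'   subject the intervals are contiguous and at most the last one
#'   carries the event.
#' @export
build_counting_process <- function(cohort,
                                   convention = "response_positive") {
  stopifnot(inherits(cohort, "br_cohort"))
  resp <- suppressMessages(compute_response(cohort, convention))
  skipped <- setdiff(cohort$baseline$subject_id, unique(resp$subject_id))
  if (length(skipped)) {
    warning(length(skipped), " subject(s) without response series skipped;",
            " run apply_eligibility() first", call. = FALSE)
  }
  resp |>
    dplyr::inner_join(
      dplyr::select(cohort$events, "subject_id", end = "event_time_years",
                    ind = "event_indicator"),
      by = "subject_id"
    ) |>
    dplyr::filter(.data$time_years < .data$end) |>
    dplyr::arrange(.data$subject_id, .data$time_years) |>
    dplyr::mutate(
      start = .data$time_years,
      stop = dplyr::lead(.data$time_years, default = Inf),
      .by = "subject_id"
    ) |>
    dplyr::mutate(
      stop = pmin(.data$stop, .data$end),
      event_in_interval = as.integer(.data$ind == 1 & .data$stop == .data$end &
                                       .data$stop < Inf)
    ) |>
    dplyr::filter(.data$start < .data$stop) |>
    dplyr::select("subject_id", "start", "stop", "event_in_interval",
                  response_at_start = "response", "baseline_hba1c")
}

#' Build the landmark analysis table
#'
#' Keeps subjects who are event-free (and uncensored) at the landmark
#' time and have a measurement within `landmark` &plusmn; `window`; the
#' exposure is the response at the measurement nearest the landmark
#' (ties resolved to the earlier one). Entry time is the landmark
#' (delayed entry).
#'
#' @param cohort A [br_cohort()].
#' @param landmark Landmark time in years (default 6 months).
#' @param window Half-width of the measurement window in years (default
#'   45 days).
#' @param convention Sign convention passed to [compute_response()].
#' @return Tibble with columns `subject_id`, `entry`, `time`, `event`,
#'   `response_landmark`, `measurement_time`, `baseline_hba1c`.
#' @export
landmark_dataset <- function(cohort, landmark = 0.5, window = 45 / 365.25,
                             convention = "response_positive") {
  stopifnot(inherits(cohort, "br_cohort"), landmark > 0, window >= 0)
  resp <- suppressMessages(compute_response(cohort, convention))
  at_risk <- cohort$events |>
    dplyr::filter(.data$event_time_years > landmark)
  resp |>
    dplyr::inner_join(
      dplyr::select(at_risk, "subject_id", time = "event_time_years",
                    event = "event_indicator"),
      by = "subject_id"
    ) |>
    dplyr::filter(abs(.data$time_years - landmark) <= window + 1e-12) |>
    dplyr::arrange(abs(.data$time_years - landmark), .data$time_years) |>
    dplyr::slice_head(n = 1, by = "subject_id") |>
    dplyr::transmute(
      .data$subject_id,
      entry = landmark,
      .data$time,
      .data$event,
      response_landmark = .data$response,
      measurement_time = .data$time_years,
      .data$baseline_hba1c
    ) |>
    dplyr::arrange(.data$subject_id)
}
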