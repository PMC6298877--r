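#' Trial cohort container
#'
#' A `br_cohort` bundles the three long-format tables that describe a
#' trial cohort: repeated HbA1c measurements, baseline covariates, and
#' first-side-effect times. The same structure is produced by the
#' synthetic generator and accepted for real data read from delimited
#' files.
#'
#' @param measurements Tibble with columns `subject_id`, `time_years`,
#'   `hba1c_pct` (raw HbA1c at post-baseline visits).
#' @param baseline Tibble with columns `subject_id`, `arm`,
#'   `baseline_hba1c_pct`, `pre_trial_history` (logical).
#' @param events Tibble with columns `subject_id`, `event_time_years`,
#'   `event_indicator` (0/1), `severity` (`mild`/`moderate`/`severe` or
#'   `NA` for censored subjects).
#' @param config Optional [sim_config()] that generated the cohort.
#' @return An object of class `br_cohort`.
#' @export
br_cohort <- function(measurements, baseline, events, config = NULL) {
  measurements <- tibble::as_tibble(measurements)
  baseline <- tibble::as_tibble(baseline)
  events <- tibble::as_tibble(events)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table lacks column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(measurements, c("subject_id", "time_years", "hba1c_pct"), "measurements")
  need(baseline, c("subject_id", "arm", "baseline_hba1c_pct",
                   "pre_trial_history"), "baseline")
  need(events, c("subject_id", "event_time_years", "event_indicator",
                 "severity"), "events")
  if (any(events$event_time_years <= 0)) {
    stop("event/censoring times must be positive", call. = FALSE)
  }
  if (!all(events$event_indicator %in% c(0, 1))) {
    stop("event_indicator must be 0/1", call. = FALSE)
  }
  if (any(!is.finite(measurements$hba1c_pct))) {
    stop("non-finite HbA1c values", call. = FALSE)
  }
  structure(list(measurements = measurements, baseline = baseline,
                 events = events, config = config),
            class = "br_cohort")
}

#' @export
print.br_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  ne <- sum(x$events$event_indicator)
  cat(sprintf("<br_cohort> %d subjects, %d measurements, %d events (%.1f%%)\n",
              n, nrow(x$measurements), ne, 100 * ne / max(n, 1)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A [br_cohort()].
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$baseline)

#' Write a cohort to delimited text files
#'
#' Writes `measurements.csv`, `baseline.csv` and `events.csv` (UTF-8,
#' comma-separated, header row) into `dir`, plus `sim_config.yaml` when
#' the cohort carries its generating configuration.
#'
#' @param cohort A [br_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "br_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(cohort$baseline, file.path(dir, "baseline.csv"))
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  if (!is.null(cohort$config)) {
    write_sim_config(cohort$config, file.path(dir, "sim_config.yaml"))
  }
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Counterpart of [write_cohort()]; also accepts real trial extracts in
#' the same schema. Times are expected in years (divide days by 365.25
#' on export from day-scaled sources).
#'
#' @param dir Directory containing `measurements.csv`, `baseline.csv`,
#'   `events.csv` and optionally `sim_config.yaml`.
#' @return A [br_cohort()].
#' @export
read_cohort <- function(dir) {
  spec_m <- readr::cols(subject_id = "i", time_years = "d", hba1c_pct = "d")
  spec_b <- readr::cols(subject_id = "i", arm = "c",
                        baseline_hba1c_pct = "d", pre_trial_history = "l")
  spec_e <- readr::cols(subject_id = "i", event_time_years = "d",
                        event_indicator = "d", severity = "c")
  cfg <- NULL
  cfg_path <- file.path(dir, "sim_config.yaml")
  if (file.exists(cfg_path)) cfg <- read_sim_config(cfg_path)
  br_cohort(
    readr::read_csv(file.path(dir, "measurements.csv"), col_types = spec_m),
    readr::read_csv(file.path(dir, "baseline.csv"), col_types = spec_b),
    readr::read_csv(file.path(dir, "events.csv"), col_types = spec_e),
    config = cfg
  )
}
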