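#' Cognitive bias index
#'
#' The cognitive bias index (CBI) for a probe session is the proportion of
#' midpoint-tone responses made on the high-reward lever minus the proportion
#' made on the low-reward lever, a score between -1 (fully pessimistic) and
#' +1 (fully optimistic). The denominator counts lever responses only;
#' omissions and premature responses are excluded, so CBI reflects choice
#' composition, not responsiveness.
#'
#' @param trials A trial tibble covering one or more probe sessions.
#' @return A tibble with one row per subject x session: `subject_id`,
#'   `session_id`, `condition`, `cbi`, `n_responded` (midpoint lever
#'   responses). Errors if any session has no midpoint lever response.
#' @examples
#' coh <- simulate_cohort(2, "vehicle", seed = 42)
#' cbi(coh)
#' @export
cbi <- function(trials) {
  out <- trials %>%
    filter(.data$session_type == "probe") %>%
    group_by(.data$subject_id, .data$session_id, .data$condition) %>%
    summarise(
      n_high = sum(.data$tone == "midpoint" & .data$response == "high_lever"),
      n_low = sum(.data$tone == "midpoint" & .data$response == "low_lever"),
      .groups = "drop"
    ) %>%
    mutate(
      n_responded = .data$n_high + .data$n_low,
      cbi = (.data$n_high - .data$n_low) / .data$n_responded
    )
  if (any(out$n_responded == 0)) {
    bad <- out %>% filter(.data$n_responded == 0)
    abort(paste0("CBI undefined (no midpoint lever responses) for ",
                 paste(paste(bad$subject_id, bad$session_id, sep = "/"),
                       collapse = ", ")),
          class = "jbtddm_undefined_metric_error")
  }
  select(out, "subject_id", "session_id", "condition", "cbi", "n_responded")
}

#' Change from baseline
#'
#' Per-subject difference of a metric between a condition and its baseline
#' (vehicle or pre-drug) value: `drug - baseline`, so a positive delta means
#' a more positive bias under drug. Used for CBI and for fitted diffusion
#' parameters alike.
#'
#' @param data Tibble with one row per subject x condition.
#' @param value Name of the value column (string).
#' @param condition Name of the condition column.
#' @param baseline Baseline level of the condition column.
#' @param subject Name of the subject column.
#' @return Tibble with `subject_id`, one column per non-baseline condition
#'   level removed, and `delta = value - baseline value`.
#' @export
change_from_baseline <- function(data, value = "cbi",
                                 condition = "condition",
                                 baseline = "vehicle",
                                 subject = "subject_id") {
  stopifnot(value %in% names(data), condition %in% names(data))
  wide <- data %>%
    select(dplyr::all_of(c(subject, condition, value))) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(condition),
                       values_from = dplyr::all_of(value))
  if (!baseline %in% names(wide))
    abort(paste0("baseline condition not present: ", baseline),
          class = "jbtddm_schema_error")
  others <- setdiff(names(wide), c(subject, baseline))
  if (length(others) != 1)
    abort("expected exactly one non-baseline condition",
          class = "jbtddm_schema_error")
  tibble(
    subject_id = wide[[subject]],
    condition = others,
    delta = wide[[others]] - wide[[baseline]]
  )
}

#' Vehicle-centred CBI
#'
#' Centres each subject's vehicle-session CBI on the cohort's vehicle mean
#' (each rat's score minus the population average for the same session),
#' providing a vehicle-session value that can enter repeated-measures
#' analyses alongside change-from-baseline scores. Output sums to zero.
#'
#' @param cbi_tbl Output of [cbi()] restricted to vehicle sessions, or any
#'   tibble with `subject_id` and `cbi`.
#' @return Tibble `subject_id`, `cbi_centred`.
#' @export
vehicle_centered_cbi <- function(cbi_tbl) {
  stopifnot(all(c("subject_id", "cbi") %in% names(cbi_tbl)))
  if (nrow(cbi_tbl) < 2)
    warn("single subject: vehicle-centred CBI is degenerate (all zero)")
  tibble(
    subject_id = cbi_tbl$subject_id,
    cbi_centred = cbi_tbl$cbi - mean(cbi_tbl$cbi)
  )
}

#' Per-tone behavioural percentages and latencies
#'
#' For each subject x session x tone: percentage of positive (high-lever)
#' responses among lever responses, percentage omissions and prematures among
#' scheduled trials of that tone, and the median and mean response latency
#' over lever responses. Cells with no lever response report `NA` (undefined),
#' never zero.
#'
#' @param trials A trial tibble.
#' @return Tibble, one row per subject x session x tone.
#' @export
bias_summary <- function(trials) {
  trials %>%
    group_by(.data$subject_id, .data$session_id, .data$condition,
             .data$session_type, .data$tone) %>%
    summarise(
      n_scheduled = n(),
      n_responded = sum(.data$response %in% c("high_lever", "low_lever")),
      pct_positive = ifelse(
        n_responded > 0,
        100 * sum(.data$response == "high_lever") / n_responded,
        NA_real_),
      pct_omission = 100 * sum(.data$response == "omission") / n(),
      pct_premature = 100 * sum(.data$response == "premature") / n(),
      median_latency = median(.data$rt, na.rm = TRUE),
      mean_latency = mean(.data$rt, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Quality-control filter
#'
#' Subjects are excluded if, in any session, their accuracy on the reference
#' tones (correct-lever responses among reference-tone lever responses) is
#' not strictly above the threshold (default 60%, read strictly: exactly 60%
#' excludes). Subjects with no reference-tone lever responses in a session
#' are excluded with that reason.
#'
#' @param trials A trial tibble covering each subject's history.
#' @param threshold Accuracy threshold as a proportion (default 0.60).
#' @return Tibble `subject_id`, `include`, `reason` (NA when included),
#'   `min_accuracy`, `worst_session`.
#' @export
qc_filter <- function(trials, threshold = .qc_threshold) {
  acc <- trials %>%
    filter(.data$tone %in% c("high", "low")) %>%
    group_by(.data$subject_id, .data$session_id) %>%
    summarise(
      n_lever = sum(.data$response %in% c("high_lever", "low_lever")),
      n_correct = sum((.data$tone == "high" & .data$response == "high_lever") |
                        (.data$tone == "low" & .data$response == "low_lever")),
      accuracy = ifelse(n_lever > 0, n_correct / n_lever, NA_real_),
      .groups = "drop"
    )
  acc %>%
    group_by(.data$subject_id) %>%
    summarise(
      no_resp = any(.data$n_lever == 0),
      min_accuracy = ifelse(all(.data$n_lever == 0), NA_real_,
                            min(.data$accuracy, na.rm = TRUE)),
      worst_session = .data$session_id[
        if (all(is.na(.data$accuracy))) 1L else which.min(.data$accuracy)],
      .groups = "drop"
    ) %>%
    mutate(
      include = !.data$no_resp & .data$min_accuracy > threshold,
      reason = dplyr::case_when(
        .data$no_resp ~ "no reference-tone lever responses",
        .data$min_accuracy <= threshold ~
          sprintf("accuracy %.1f%% <= %.0f%% in session %s",
                  100 * .data$min_accuracy, 100 * threshold,
                  .data$worst_session),
        TRUE ~ NA_character_
      )
    ) %>%
    select("subject_id", "include", "reason", "min_accuracy",
           "worst_session")
}
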