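#' Write and read trial logs
#'
#' Trial logs are plain CSV, one row per trial, UTF-8, header required, RT in
#' seconds. `read_trial_log()` validates every record against the task
#' contract and fails with line-numbered messages: tones must be
#' high/midpoint/low, responses high_lever/low_lever/omission/premature, RT
#' present if and only if the response is a lever press and within the 20 s
#' response window, baseline sessions must hold exactly 100 trials (50/50)
#' and probe sessions exactly 120 (40/40/40).
#'
#' @param trials A trial tibble as produced by [simulate_session()].
#' @param path File path.
#' @return `read_trial_log()` returns the validated trial tibble;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
write_trial_log <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path))
    abort(paste0("cannot read trial log: ", path), class = "jbtddm_io_error")
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      session_id = readr::col_character(),
      condition = readr::col_character(),
      session_type = readr::col_character(),
      trial_index = readr::col_integer(),
      tone = readr::col_character(),
      tone_hz = readr::col_double(),
      response = readr::col_character(),
      rt = readr::col_double(),
      reinforced_as = readr::col_character()
    ),
    na = c("", "NA")
  )
  validate_trials(trials)
  trials
}

# Full trial-log validation; aborts with line-numbered messages (line 1 is
# the CSV header, so data row i is line i + 1).
validate_trials <- function(trials) {
  required <- c("subject_id", "session_id", "condition", "session_type",
                "trial_index", "tone", "response", "rt", "reinforced_as")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0)
    abort(paste0("trial log missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "jbtddm_validation_error")
  line <- seq_len(nrow(trials)) + 1L
  fail <- function(rows, what) {
    abort(paste0("invalid trial log: ", what, " at line(s) ",
                 paste(utils::head(line[rows], 5), collapse = ", "),
                 if (sum(rows) > 5) " ..." else ""),
          class = "jbtddm_validation_error")
  }
  bad <- !trials$tone %in% .tones
  if (any(bad)) fail(bad, "unknown tone label")
  bad <- !trials$response %in% .responses
  if (any(bad)) fail(bad, "unknown response label")
  lever <- trials$response %in% c("high_lever", "low_lever")
  bad <- lever & is.na(trials$rt)
  if (any(bad)) fail(bad, "lever response without RT")
  bad <- !lever & !is.na(trials$rt)
  if (any(bad)) fail(bad, "RT recorded for non-lever response")
  bad <- !is.na(trials$rt) & (trials$rt <= 0 | trials$rt > .response_window)
  if (any(bad))
    fail(bad, sprintf("RT outside (0, %d] s response window",
                      .response_window))
  bad <- !trials$reinforced_as %in% c("high", "low")
  if (any(bad)) fail(bad, "unknown reinforced_as label")

  # session-level structural counts
  sess <- trials %>%
    group_by(.data$subject_id, .data$session_id, .data$session_type) %>%
    summarise(
      n = n(),
      n_high = sum(.data$tone == "high"),
      n_mid = sum(.data$tone == "midpoint"),
      n_low = sum(.data$tone == "low"),
      .groups = "drop"
    )
  bad_sess <- sess %>%
    filter(
      (.data$session_type == "baseline" &
         !(.data$n == 100 & .data$n_high == 50 & .data$n_low == 50 &
             .data$n_mid == 0)) |
      (.data$session_type == "probe" &
         !(.data$n == 120 & .data$n_high == 40 & .data$n_mid == 40 &
             .data$n_low == 40)) |
      !.data$session_type %in% c("baseline", "probe")
    )
  if (nrow(bad_sess) > 0)
    abort(paste0(
      "invalid trial log: session trial counts violate the task structure ",
      "for ", paste(paste(bad_sess$subject_id, bad_sess$session_id,
                          sep = "/"), collapse = ", ")),
      class = "jbtddm_validation_error")
  invisible(trials)
}
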