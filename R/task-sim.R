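#' Build a pseudorandom tone schedule
#'
#' Baseline sessions present 100 reference tones (50 high-reward, 50
#' low-reward); probe sessions present 120 tones (40 high, 40 ambiguous
#' midpoint, 40 low). "Pseudorandom" is implemented as a uniformly random
#' permutation rejected until no tone repeats more than 4 times in a row.
#'
#' @param type `"baseline"` or `"probe"`.
#' @param seed Integer seed; the same seed always yields the same schedule.
#' @param max_run Longest permitted run of one tone.
#' @return Character vector of tones (`"high"`, `"midpoint"`, `"low"`).
#' @export
build_schedule <- function(type = c("probe", "baseline"), seed,
                           max_run = 4) {
  type <- match.arg(type)
  tones <- if (type == "baseline") {
    rep(c("high", "low"), each = 50)
  } else {
    rep(c("high", "midpoint", "low"), each = 40)
  }
  withr::with_seed(as.integer(seed), {
    repeat {
      sched <- sample(tones)
      runs <- rle(sched)
      if (max(runs$lengths) <= max_run) break
    }
    sched
  })
}

#' Specify a synthetic subject
#'
#' A forward model of one rat: a [ddm_params()] set per tone plus omission
#' and premature-response rates. The upper boundary is the high-reward lever
#' everywhere. Omissions arise both from the explicit per-tone omission
#' probability and from censoring at the 20 s response window; premature
#' responses occur with a flat per-trial probability before the tone is
#' processed and carry no RT.
#'
#' @param id Subject label.
#' @param high,midpoint,low [ddm_params()] for each tone.
#' @param omission_rate Per-tone omission probability; scalar or named
#'   vector over tones.
#' @param premature_rate Per-trial premature-response probability.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(id, high, midpoint, low,
                         omission_rate = 0.05, premature_rate = 0.03) {
  pars <- list(high = high, midpoint = midpoint, low = low)
  for (p in pars) validate_ddm_params(as_par_vector(p))
  if (length(omission_rate) == 1)
    omission_rate <- stats::setNames(rep(omission_rate, 3), .tones)
  stopifnot(all(.tones %in% names(omission_rate)),
            all(omission_rate >= 0 & omission_rate <= 1),
            premature_rate >= 0, premature_rate <= 1)
  structure(list(id = as.character(id), params = pars,
                 omission_rate = omission_rate[.tones],
                 premature_rate = premature_rate),
            class = "subject_spec")
}

#' Simulate one task session
#'
#' Generates a full trial log for one subject and session. Each scheduled
#' tone is, with probability `premature_rate`, recorded as a premature
#' response (no RT); otherwise a (lever, RT) pair is drawn from the tone's
#' diffusion process. Draws exceeding the 20 s response window, or an
#' explicit omission draw, are recorded as omissions. Midpoint-tone outcomes
#' are randomly reinforced: `reinforced_as` is high or low with equal
#' probability, so no specific outcome can be learned; the two midpoint tone
#' frequencies (4999/5001 Hz) are balanced 20/20 and carried as metadata.
#'
#' @param spec A [subject_spec()].
#' @param type `"probe"` or `"baseline"`.
#' @param session_id Session label.
#' @param condition Condition label (e.g. drug dose), free text.
#' @param seed Integer seed; sessions are reproducible from it.
#' @return A tibble of trial records: `subject_id`, `session_id`,
#'   `condition`, `session_type`, `trial_index`, `tone`, `tone_hz`,
#'   `response`, `rt`, `reinforced_as`.
#' @export
simulate_session <- function(spec, type = c("probe", "baseline"),
                             session_id = "s1", condition = "vehicle",
                             seed = 1) {
  type <- match.arg(type)
  stopifnot(inherits(spec, "subject_spec"))
  sched <- build_schedule(type, seed = seed)
  n <- length(sched)
  withr::with_seed(as.integer(seed) + 1L, {
    # midpoint frequency variants balanced within session
    tone_hz <- ifelse(sched == "high", 2000, ifelse(sched == "low", 8000, NA))
    mid_idx <- which(sched == "midpoint")
    if (length(mid_idx) > 0) {
      hz <- sample(rep(c(4999, 5001), length.out = length(mid_idx)))
      tone_hz[mid_idx] <- hz
    }
    premature <- stats::runif(n) < spec$premature_rate
    response <- character(n)
    rt <- rep(NA_real_, n)
    for (tone in .tones) {
      idx <- which(sched == tone & !premature)
      if (length(idx) == 0) next
      draw <- ddm_sample(spec$params[[tone]], length(idx))
      omit <- stats::runif(length(idx)) < spec$omission_rate[[tone]] |
        draw$rt > .response_window
      response[idx] <- ifelse(
        omit, "omission",
        ifelse(draw$boundary == "upper", "high_lever", "low_lever"))
      rt[idx] <- ifelse(omit, NA_real_, draw$rt)
    }
    response[premature] <- "premature"
    reinforced <- ifelse(sched == "high", "high",
                         ifelse(sched == "low", "low", NA))
    mid <- which(sched == "midpoint")
    reinforced[mid] <- sample(c("high", "low"), length(mid), replace = TRUE)
    tibble(
      subject_id = spec$id,
      session_id = as.character(session_id),
      condition = as.character(condition),
      session_type = type,
      trial_index = seq_len(n),
      tone = sched,
      tone_hz = tone_hz,
      response = response,
      rt = rt,
      reinforced_as = reinforced
    )
  })
}

# Realistic per-subject baseline parameters for a well-trained, mildly
# negatively biased rat; heterogeneity ranges are drawn per subject.
draw_baseline_params <- function() {
  a <- stats::runif(1, 1.4, 2.2)
  zr <- stats::runif(1, 0.42, 0.58)
  t0 <- stats::runif(1, 0.6, 1.0)
  list(
    a = a, zr = zr, t0 = t0,
    v_high = stats::runif(1, 0.9, 1.6),
    v_mid = -stats::runif(1, 0.4, 1.2),
    v_low = -stats::runif(1, 0.9, 1.6)
  )
}

subject_from_base <- function(id, base, v_mid_shift = 0, zr_shift = 0) {
  zr <- min(max(base$zr + zr_shift, 0.05), 0.95)
  mk <- function(v) ddm_params(a = base$a, zr = zr, v = v, t0 = base$t0)
  subject_spec(id,
               high = mk(base$v_high),
               midpoint = mk(base$v_mid + v_mid_shift),
               low = mk(base$v_low))
}

#' Simulate a paired vehicle/drug cohort
#'
#' Generates the within-subject design used for acute drug studies: each
#' subject contributes one vehicle probe session and one drug probe session
#' (plus optional baseline sessions). Presets inject the drug effect into
#' the decision process: `"v_shift"` adds `delta` to the midpoint-tone drift
#' rate (the rapid-antidepressant signature), `"zr_shift"` adds `delta` to
#' the session-wide relative starting point (the delayed-antidepressant
#' signature), `"vehicle"` injects nothing — its drug session has identical
#' parameters, giving genuine null change-from-baseline scores for
#' calibration. Per-subject baseline parameters are drawn from realistic
#' ranges so cohorts carry individual differences.
#'
#' @param n_subjects Number of subjects (the drug studies used 9-17).
#' @param preset `"vehicle"`, `"v_shift"` or `"zr_shift"`.
#' @param delta Effect size applied by the preset (drift units, or starting-
#'   point fraction). Defaults: 0.6 for `v_shift`, 0.05 for `zr_shift`.
#' @param seed Integer seed for the whole cohort.
#' @param n_baseline Baseline sessions per subject (default 0).
#' @return A tibble of trial records with paired `"vehicle"` and `"drug"`
#'   conditions per subject.
#' @export
simulate_cohort <- function(n_subjects,
                            preset = c("vehicle", "v_shift", "zr_shift"),
                            delta = NULL, seed = 1, n_baseline = 0) {
  if (n_subjects < 1)
    abort("`n_subjects` must be >= 1", class = "jbtddm_argument_error")
  preset <- match.arg(preset)
  if (is.null(delta))
    delta <- switch(preset, vehicle = 0, v_shift = 0.6, zr_shift = 0.05)
  seed <- as.integer(seed)
  bases <- withr::with_seed(seed, {
    purrr::map(seq_len(n_subjects), ~draw_baseline_params())
  })
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    id <- sprintf("r%02d", i)
    base <- bases[[i]]
    veh <- subject_from_base(id, base)
    drg <- switch(preset,
      vehicle = subject_from_base(id, base),
      v_shift = subject_from_base(id, base, v_mid_shift = delta),
      zr_shift = subject_from_base(id, base, zr_shift = delta))
    sseed <- seed + 1000L * i
    out <- list()
    if (n_baseline > 0) {
      out <- purrr::map(seq_len(n_baseline), function(b)
        simulate_session(veh, "baseline", sprintf("base%d", b), "vehicle",
                         seed = sseed + 100L + b))
    }
    out <- c(out, list(
      simulate_session(veh, "probe", "probe_vehicle", "vehicle",
                       seed = sseed),
      simulate_session(drg, "probe", "probe_drug", "drug",
                       seed = sseed + 1L)))
    bind_rows(out)
  })
}
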