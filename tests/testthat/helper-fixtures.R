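# Hand-constructed trial tibbles used across the metric and fitting tests.

# A structurally valid probe session with scripted midpoint responses.
# mid_high / mid_low: lever counts at the midpoint tone; remaining midpoint
# trials are omissions. Reference tones respond on the correct lever with
# probability `ref_acc` (deterministic counts, not random).
make_probe_session <- function(subject = "r01", session = "s1",
                               condition = "vehicle",
                               mid_high = 20, mid_low = 20,
                               ref_acc = 1, rt = 2) {
  stopifnot(mid_high + mid_low <= 40)
  resp_for <- function(tone, n) {
    correct <- if (tone == "high") "high_lever" else "low_lever"
    wrong <- if (tone == "high") "low_lever" else "high_lever"
    n_ok <- round(ref_acc * n)
    c(rep(correct, n_ok), rep(wrong, n - n_ok))
  }
  mid_resp <- c(rep("high_lever", mid_high), rep("low_lever", mid_low),
                rep("omission", 40 - mid_high - mid_low))
  tones <- rep(c("high", "midpoint", "low"), each = 40)
  response <- c(resp_for("high", 40), mid_resp, resp_for("low", 40))
  tibble::tibble(
    subject_id = subject,
    session_id = session,
    condition = condition,
    session_type = "probe",
    trial_index = seq_along(tones),
    tone = tones,
    tone_hz = ifelse(tones == "high", 2000,
                     ifelse(tones == "low", 8000, 5001)),
    response = response,
    rt = ifelse(response %in% c("high_lever", "low_lever"), rt, NA_real_),
    reinforced_as = ifelse(tones == "low", "low", "high")
  )
}

# Minimal jbt_fit object with given midpoint parameters (for delta tests).
make_fit <- function(v = -0.8, a = 1.2, zr = 0.5, t0 = 0.3) {
  structure(list(
    params = tibble::tibble(tone = c("high", "midpoint", "low"),
                            a = a, zr = zr, v = c(1.2, v, -1.2), t0 = t0,
                            d = 0, szr = 0, sv = 0, st0 = 0),
    shared_params = c("zr", "t0"),
    fixed_params = c(d = 0, szr = 0, sv = 0, st0 = 0),
    ks_statistic = 0.05, converged = TRUE, n_evaluations = 100L,
    n_trials_used = tibble::tibble(tone = c("high", "midpoint", "low"),
                                   n = 40L),
    removed = c(omission = 0L, premature = 0L),
    subject_id = "r01", session_id = "s1", condition = "vehicle"
  ), class = "jbt_fit")
}

# Trials tibble from raw (boundary, rt) draws, for fitting synthetic data
# generated straight from the diffusion sampler.
draws_to_trials <- function(draws, tone = "midpoint", subject = "r01",
                            session = "s1", condition = "vehicle") {
  tibble::tibble(
    subject_id = subject, session_id = session, condition = condition,
    session_type = "probe", trial_index = seq_len(nrow(draws)),
    tone = tone,
    tone_hz = 5001,
    response = ifelse(draws$boundary == "upper", "high_lever", "low_lever"),
    rt = draws$rt,
    reinforced_as = "high"
  )
}
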