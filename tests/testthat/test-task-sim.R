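test_that("schedules have exact counts and bounded runs", {
  for (seed in 1:50) {
    pr <- build_schedule("probe", seed)
    expect_length(pr, 120)
    expect_equal(unname(table(pr)[c("high", "midpoint", "low")]),
                 c(40L, 40L, 40L), ignore_attr = TRUE)
    expect_lte(max(rle(pr)$lengths), 4)
    bl <- build_schedule("baseline", seed)
    expect_length(bl, 100)
    expect_equal(sum(bl == "high"), 50)
    expect_equal(sum(bl == "low"), 50)
    expect_lte(max(rle(bl)$lengths), 4)
  }
  expect_identical(build_schedule("probe", 123), build_schedule("probe", 123))
})

well_trained <- function(id = "r01") {
  mk <- function(v) ddm_params(a = 1.8, zr = 0.5, v = v, t0 = 0.8)
  subject_spec(id, high = mk(1.2), midpoint = mk(-0.5), low = mk(-1.2),
               omission_rate = 0.05, premature_rate = 0.03)
}

test_that("sessions honour the generative contract trial by trial", {
  s <- simulate_session(well_trained(), "probe", seed = 21)
  lever <- s$response %in% c("high_lever", "low_lever")
  expect_true(all(!is.na(s$rt[lever])))
  expect_true(all(is.na(s$rt[!lever])))
  expect_true(all(s$rt[lever] > 0 & s$rt[lever] <= 20))
  expect_setequal(unique(s$reinforced_as[s$tone == "high"]), "high")
  expect_setequal(unique(s$reinforced_as[s$tone == "low"]), "low")
  # midpoint frequency variants balanced 20/20
  expect_equal(unname(table(s$tone_hz[s$tone == "midpoint"])), c(20L, 20L),
               ignore_attr = TRUE)
  expect_identical(s, simulate_session(well_trained(), "probe", seed = 21))
})

test_that("degenerate rates behave as specified", {
  spec_omit <- well_trained()
  spec_omit$omission_rate[] <- 1
  s <- simulate_session(spec_omit, "probe", seed = 3)
  expect_true(all(s$response %in% c("omission", "premature")))
  expect_error(cbi(s), class = "jbtddm_undefined_metric_error")

  spec_clean <- well_trained()
  spec_clean$omission_rate[] <- 0
  spec_clean$premature_rate <- 0
  s2 <- simulate_session(spec_clean, "probe", seed = 3)
  # DDM decision times here are far below the 20 s window, so no censoring
  expect_equal(sum(s2$response == "omission"), 0)
  expect_equal(sum(s2$response == "premature"), 0)
})

test_that("strong positive drift yields near-universal high-lever choice", {
  mk <- function(v) ddm_params(a = 1.8, zr = 0.5, v = v, t0 = 0.8)
  spec <- subject_spec("r01", high = mk(3), midpoint = mk(3), low = mk(3),
                       omission_rate = 0, premature_rate = 0)
  frac <- purrr::map_dbl(1:10, function(sd) {
    s <- simulate_session(spec, "probe", seed = sd)
    high <- s[s$tone == "high", ]
    mean(high$response == "high_lever")
  })
  expect_gt(mean(frac), 0.9)
})

test_that("midpoint reinforcement is unlearnable (50/50 in the long run)", {
  sessions <- purrr::map_dfr(1:84, function(sd)
    simulate_session(well_trained(), "probe", seed = sd,
                     session_id = paste0("s", sd)))
  mid <- sessions[sessions$tone == "midpoint", ]
  n <- nrow(mid)
  expect_gte(n, 1e4 * 0.336)  # 40 midpoint trials per session
  frac <- mean(mid$reinforced_as == "high")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("generated RTs agree with the generating diffusion CDF (KS)", {
  p <- ddm_params(a = 1.8, zr = 0.5, v = -0.5, t0 = 0.8)
  mk0 <- function() subject_spec("r01", high = p, midpoint = p, low = p,
                                 omission_rate = 0, premature_rate = 0)
  sessions <- purrr::map_dfr(1:84, function(sd)
    simulate_session(mk0(), "probe", seed = sd,
                     session_id = paste0("s", sd)))
  rts <- sort(sessions$rt[sessions$response == "high_lever"])
  n <- length(rts)
  Fc <- ddm_cdf(p, rts, "upper") / ddm_absorption(p, "upper")
  D <- max(pmax(abs(Fc - seq_len(n) / n), abs(Fc - (seq_len(n) - 1) / n)))
  expect_lt(D, 1.628 / sqrt(n))  # alpha = 0.01
})

test_that("trial logs round-trip through CSV losslessly", {
  coh <- simulate_cohort(2, "v_shift", seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(coh, path)
  back <- read_trial_log(path)
  expect_equal(as.data.frame(back), as.data.frame(coh))
})

test_that("the reader rejects malformed logs with located errors", {
  coh <- simulate_cohort(1, "vehicle", seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")

  # a probe session with 119 rows
  write_trial_log(coh, path)
  lines <- readLines(path)
  writeLines(lines[-2], path)
  expect_error(read_trial_log(path), "counts",
               class = "jbtddm_validation_error")

  # RT beyond the 20 s response window
  bad_rt <- coh
  i <- which(!is.na(bad_rt$rt))[1]
  bad_rt$rt[i] <- 25
  expect_error(validate_trials(bad_rt), "window",
               class = "jbtddm_validation_error")

  # unknown tone label, reported with its line number
  bad_tone <- coh
  bad_tone$tone[3] <- "weird"
  err <- tryCatch(validate_trials(bad_tone), error = function(e) e)
  expect_s3_class(err, "jbtddm_validation_error")
  expect_match(conditionMessage(err), "line\\(s\\) 4")
})

test_that("cohort presets produce paired sessions and valid arguments", {
  expect_error(simulate_cohort(0, "vehicle"), class = "jbtddm_argument_error")
  expect_error(simulate_cohort(2, "nonsense"))
  coh <- simulate_cohort(1, "zr_shift", seed = 2)
  expect_setequal(unique(coh$condition), c("vehicle", "drug"))
  expect_equal(nrow(coh), 240)
  # a drift shift at the midpoint moves cohort-mean delta CBI upward (smoke)
  set.seed(1)
  coh_v <- simulate_cohort(8, "v_shift", delta = 0.8, seed = 31)
  d <- change_from_baseline(cbi(coh_v))
  expect_gt(mean(d$delta), 0)
})

test_that("a drift-rate shift moves cohort-mean CBI change in nearly every cohort", {
  pos <- purrr::map_lgl(1:100, function(r) {
    coh <- simulate_cohort(13, "v_shift", seed = 60000 + r)
    mean(change_from_baseline(cbi(coh))$delta) > 0
  })
  expect_gte(mean(pos), 0.95)
})

test_that("a zero shift leaves change-from-baseline CBI at its nominal type-I rate", {
  rej <- purrr::map_lgl(1:500, function(r) {
    coh <- simulate_cohort(13, "zr_shift", delta = 0, seed = 70000 + r)
    one_sample_t(change_from_baseline(cbi(coh))$delta)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})
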