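test_that("one-sample t-test handles the degenerate and symmetric cases", {
  zeros <- one_sample_t(rep(0, 8))
  expect_true(zeros$degenerate)
  expect_true(is.na(zeros$statistic))

  sym <- one_sample_t(c(1, -1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  set.seed(1)
  x <- rnorm(13, 0.3)
  ours <- one_sample_t(x)
  ref <- t.test(x, mu = 0)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  expect_error(one_sample_t(1), class = "jbtddm_argument_error")
})

# a balanced subject x session x tone table
rm_table <- function(n_subj = 6, sessions = 3, tones = 3, effect = 0,
                     seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(
    subject_id = sprintf("s%02d", seq_len(n_subj)),
    session_id = paste0("sess", seq_len(sessions)),
    tone = paste0("tone", seq_len(tones))
  ) %>%
    dplyr::mutate(value = rnorm(dplyr::n()) +
                    effect * (session_id == "sess2"))
}

test_that("repeated-measures ANOVA gives F = 0 for constant within-subject data", {
  tbl <- rm_table()
  const <- tbl %>%
    dplyr::group_by(subject_id) %>%
    dplyr::mutate(value = value[1]) %>%
    dplyr::ungroup()
  # car warns that sphericity tests are unavailable on zero-variance data
  res <- suppressWarnings(rm_anova(const, within = c("session_id", "tone")))
  expect_equal(res$statistic[res$effect == "session_id"], 0,
               tolerance = 1e-10)
})

test_that("two-level within factors need no sphericity correction", {
  tbl <- rm_table(sessions = 2, tones = 1) %>% dplyr::select(-tone)
  res <- rm_anova(tbl, within = "session_id")
  expect_equal(res$correction, "none")
  expect_equal(res$df1, 1)
})

test_that("repeated-measures F agrees with the aov() oracle", {
  tbl <- rm_table(n_subj = 6, sessions = 3, tones = 1, effect = 0.8) %>%
    dplyr::select(-tone)
  ours <- rm_anova(tbl, within = "session_id")
  oracle <- summary(stats::aov(
    value ~ session_id + Error(subject_id / session_id), data = tbl))
  f_oracle <- oracle[["Error: subject_id:session_id"]][[1]]["session_id",
                                                           "F value"]
  expect_equal(ours$statistic, f_oracle, tolerance = 1e-6)
  # two-factor design, both main effects
  tbl2 <- rm_table(n_subj = 6, effect = 0.5)
  ours2 <- rm_anova(tbl2, within = c("session_id", "tone"))
  oracle2 <- summary(stats::aov(
    value ~ session_id * tone +
      Error(subject_id / (session_id * tone)), data = tbl2))
  f_sess <- oracle2[["Error: subject_id:session_id"]][[1]]["session_id",
                                                           "F value"]
  f_tone <- oracle2[["Error: subject_id:tone"]][[1]]["tone      ",
                                                     "F value"]
  if (is.na(f_tone))
    f_tone <- oracle2[["Error: subject_id:tone"]][[1]][1, "F value"]
  expect_equal(ours2$statistic[ours2$effect == "session_id"], f_sess,
               tolerance = 1e-6)
  expect_equal(ours2$statistic[ours2$effect == "tone"], f_tone,
               tolerance = 1e-6)
})

test_that("incomplete repeated-measures tables are refused", {
  tbl <- rm_table()[-1, ]
  expect_error(rm_anova(tbl, within = c("session_id", "tone")),
               class = "jbtddm_schema_error")
  dup <- dplyr::bind_rows(rm_table(), rm_table()[1, ])
  expect_error(rm_anova(dup, within = c("session_id", "tone")),
               class = "jbtddm_schema_error")
})

test_that("mixed ANOVA detects groups and degenerates correctly", {
  base <- rm_table(n_subj = 8)
  # identical groups: between-subjects F is exactly 0
  dup <- dplyr::bind_rows(
    base %>% dplyr::mutate(group = "g1"),
    base %>% dplyr::mutate(subject_id = paste0(subject_id, "b"),
                           group = "g2"))
  res <- mixed_anova(dup, within = c("session_id", "tone"))
  expect_equal(res$statistic[res$effect == "group"], 0, tolerance = 1e-10)

  # F(group) grows monotonically with an injected offset
  fs <- purrr::map_dbl(c(0.3, 0.8, 1.5), function(delta) {
    shifted <- dup %>%
      dplyr::mutate(value = value + delta * (group == "g2"))
    r <- mixed_anova(shifted, within = c("session_id", "tone"))
    r$statistic[r$effect == "group"]
  })
  expect_true(all(diff(fs) > 0))

  solo <- dplyr::bind_rows(
    base %>% dplyr::mutate(group = "g1"),
    rm_table(n_subj = 1, seed = 2) %>%
      dplyr::mutate(subject_id = "only", group = "g2"))
  expect_error(mixed_anova(solo, within = c("session_id", "tone")),
               class = "jbtddm_argument_error")
})

test_that("post-hoc tests gate on Levene and adjust with Bonferroni", {
  x <- c(1.2, 0.8, 1.1, 0.9, 1.0)
  same <- posthoc(x, x, "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_adjusted, 1)
  expect_true(same$degenerate)

  set.seed(3)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  res <- posthoc(a, b, "paired", m_comparisons = 3)
  expect_equal(res$p_adjusted, min(1, 3 * res$p_value))

  # heteroscedastic input (10x the SD) routes to the Welch form
  set.seed(4)
  h1 <- rnorm(40, sd = 1); h2 <- rnorm(40, sd = 10)
  het <- posthoc(h1, h2, "independent")
  expect_false(het$var_equal)
  expect_lt(het$levene_p, 0.05)
  hom <- posthoc(rnorm(40), rnorm(40), "independent")
  expect_true(hom$var_equal)

  expect_error(posthoc(1:3, 1:4, "paired"), class = "jbtddm_argument_error")
})

test_that("weekly aggregation averages the two probe sessions of each week", {
  tbl <- tibble::tibble(
    subject_id = rep("r1", 4),
    session_id = paste0("s", 1:4),
    value = c(0.1, 0.3, 0.5, 0.7))
  wk <- average_by_week(tbl)
  expect_equal(wk$week, c(1, 2))
  expect_equal(wk$value, c(0.2, 0.6))
})
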