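#' One-sample t-test against zero
#'
#' Change-from-baseline scores are tested against a null value of zero (no
#' change from the vehicle or control probe session), two-sided. Zero
#' variance is flagged as degenerate rather than raising.
#'
#' @param x Numeric vector of per-subject deltas (n >= 2, finite).
#' @param mu Null value (default 0).
#' @param label Effect label carried into the result.
#' @return A one-row tibble: `effect`, `statistic`, `df`, `p_value`,
#'   `correction`, `degenerate`.
#' @export
one_sample_t <- function(x, mu = 0, label = "delta") {
  x <- x[is.finite(x)]
  if (length(x) < 2)
    abort("need at least 2 finite values", class = "jbtddm_argument_error")
  if (sd(x) == 0) {
    return(tibble(effect = label, statistic = NA_real_,
                  df = length(x) - 1, p_value = NA_real_,
                  correction = "none", degenerate = TRUE))
  }
  tt <- t.test(x, mu = mu)
  tibble(effect = label, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         correction = "none", degenerate = FALSE)
}

# Pivot a long table to the subject x cell matrix required by car::Anova,
# refusing unbalanced or incomplete designs.
rm_wide <- function(data, dv, subject, within) {
  for (col in c(dv, subject, within))
    if (!col %in% names(data))
      abort(paste0("column not found: ", col), class = "jbtddm_schema_error")
  cells <- data %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(subject, within))))
  if (any(cells$n != 1))
    abort("repeated-measures table has duplicated cells",
          class = "jbtddm_schema_error")
  wide <- data %>%
    select(dplyr::all_of(c(subject, within, dv))) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(dv),
                       names_sep = ".")
  mat <- as.matrix(wide[, setdiff(names(wide), subject)])
  if (anyNA(mat))
    abort("missing cells in repeated-measures table (design must be complete)",
          class = "jbtddm_schema_error")
  idata <- data %>%
    distinct(dplyr::across(dplyr::all_of(within))) %>%
    arrange(dplyr::across(dplyr::all_of(within))) %>%
    as.data.frame()
  # order columns to match idata
  key <- do.call(paste, c(idata, sep = "."))
  mat <- mat[, key, drop = FALSE]
  for (f in within) idata[[f]] <- factor(idata[[f]])
  list(y = mat, idata = idata, subjects = wide[[subject]])
}

# Extract a tidy effect table from car's univariate repeated-measures output.
tidy_car_univariate <- function(s, hf_gate = 0.05) {
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  purrr::map_dfr(effects, function(e) {
    f <- ut[e, "F value"]; df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    p_raw <- ut[e, "Pr(>F)"]
    if (!is.finite(f) && ut[e, "Sum Sq"] < 1e-12) {
      # no effect variance at all (0/0): report a null effect, not NaN
      f <- 0; p_raw <- 1
    }
    eps <- NA_real_; mauchly_p <- NA_real_
    if (!is.null(sph) && e %in% rownames(sph))
      mauchly_p <- sph[e, "p-value"]
    if (!is.null(adj) && e %in% rownames(adj))
      eps <- min(unname(adj[e, "HF eps"]), 1)  # clip to 1
    apply_hf <- is.finite(eps) && is.finite(mauchly_p) && mauchly_p < hf_gate
    df1c <- if (apply_hf) eps * df1 else df1
    df2c <- if (apply_hf) eps * df2 else df2
    p <- if (apply_hf) stats::pf(f, df1c, df2c, lower.tail = FALSE) else p_raw
    tibble(effect = e, statistic = unname(f),
           df1 = unname(df1), df2 = unname(df2),
           epsilon = if (is.finite(eps)) unname(eps) else NA_real_,
           df1_corrected = unname(df1c), df2_corrected = unname(df2c),
           sphericity_p = unname(mauchly_p),
           p_uncorrected = unname(p_raw), p_value = unname(p),
           correction = if (apply_hf) "HF" else "none")
  })
}

#' Repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Within-subject ANOVA over one or two repeated factors (session, tone in
#' the task's designs). Delegates the linear-model computation to
#' `car::Anova()` on a multivariate linear model (type III) and reports the
#' univariate repeated-measures effects. When Mauchly's test indicates a
#' sphericity violation (p < 0.05) the Huynh-Feldt epsilon (clipped to 1)
#' deflates the degrees of freedom and the corrected p-value is reported;
#' both raw and corrected values are always returned. With a 2-level factor
#' sphericity holds trivially and no correction applies.
#'
#' @param data Long tibble, one row per subject x within-cell; the design
#'   must be complete and balanced (missing cells are an error, never
#'   silently dropped).
#' @param dv Name of the value column.
#' @param subject Name of the subject column.
#' @param within Character vector of one or two within-subject factor columns.
#' @param hf_gate Mauchly p-value below which the HF correction is applied.
#' @return Tibble of effects: `effect`, `statistic` (F), raw and corrected
#'   df, `epsilon`, `sphericity_p`, `p_uncorrected`, `p_value`, `correction`.
#' @export
rm_anova <- function(data, dv = "value", subject = "subject_id",
                     within = c("session_id", "tone"), hf_gate = 0.05) {
  w <- rm_wide(data, dv, subject, within)
  mlm <- stats::lm(w$y ~ 1)
  idesign <- stats::as.formula(paste0("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = w$idata, idesign = idesign, type = 3)
  s <- quiet_hf(summary(av, multivariate = FALSE))
  tidy_car_univariate(s, hf_gate)
}

#' Mixed ANOVA with a between-subjects group factor
#'
#' The chronic-treatment design: repeated measures (session, tone) within
#' subjects and treatment group between subjects. Sum-to-zero contrasts are
#' used for the type III decomposition; Huynh-Feldt correction as in
#' [rm_anova()].
#'
#' @inheritParams rm_anova
#' @param between Name of the group column (>= 2 subjects per group).
#' @return Tibble of effects including the between-subjects main effect and
#'   group x within interactions.
#' @export
mixed_anova <- function(data, dv = "value", subject = "subject_id",
                        within = c("session_id", "tone"),
                        between = "group", hf_gate = 0.05) {
  if (!between %in% names(data))
    abort(paste0("column not found: ", between),
          class = "jbtddm_schema_error")
  grp_tbl <- distinct(data, dplyr::across(dplyr::all_of(c(subject, between))))
  if (any(duplicated(grp_tbl[[subject]])))
    abort("subjects must belong to exactly one group",
          class = "jbtddm_schema_error")
  if (any(table(grp_tbl[[between]]) < 2))
    abort("each group needs at least 2 subjects",
          class = "jbtddm_argument_error")
  w <- rm_wide(data, dv, subject, within)
  grp <- factor(grp_tbl[[between]][match(w$subjects, grp_tbl[[subject]])])
  y <- w$y
  mlm <- withr::with_options(
    list(contrasts = c("contr.sum", "contr.poly")),
    stats::lm(y ~ grp))
  idesign <- stats::as.formula(paste0("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = w$idata, idesign = idesign, type = 3)
  s <- quiet_hf(summary(av, multivariate = FALSE))
  out <- tidy_car_univariate(s, hf_gate)
  out$effect <- gsub("^grp", between, out$effect)
  out$effect <- gsub(":grp", paste0(":", between), out$effect)
  out
}

#' Post-hoc t-tests with Levene gating and Bonferroni adjustment
#'
#' Paired or independent-samples t-tests used after a significant omnibus
#' effect. For the independent design, Levene's test decides between the
#' equal-variance and Welch forms (unequal variances assumed when Levene's
#' p < 0.05; the routing is recorded). Bonferroni adjustment multiplies the
#' p-value by the number of comparisons, capped at 1. Identical paired
#' samples (all differences zero) are reported as t = 0, p = 1 with a
#' degenerate flag.
#'
#' @param x,y Numeric vectors (equal length for the paired design).
#' @param design `"paired"` or `"independent"`.
#' @param m_comparisons Number of comparisons in the Bonferroni family.
#' @param label Effect label.
#' @return One-row tibble: `effect`, `statistic`, `df`, `p_value` (raw),
#'   `p_adjusted`, `correction`, `var_equal`, `levene_p`, `degenerate`.
#' @export
posthoc <- function(x, y, design = c("paired", "independent"),
                    m_comparisons = 1, label = "pair") {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(x) != length(y))
      abort("paired design requires equal lengths",
            class = "jbtddm_argument_error")
    d <- x - y
    if (sd(d) == 0) {
      p_adj <- 1
      return(tibble(effect = label, statistic = 0, df = length(d) - 1,
                    p_value = 1, p_adjusted = p_adj,
                    correction = "Bonferroni", var_equal = NA,
                    levene_p = NA_real_, degenerate = TRUE))
    }
    tt <- t.test(x, y, paired = TRUE)
    lev_p <- NA_real_
    veq <- NA
  } else {
    vals <- c(x, y)
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    lev <- car::leveneTest(vals ~ g)
    lev_p <- lev[["Pr(>F)"]][1]
    veq <- lev_p >= 0.05
    tt <- t.test(x, y, var.equal = veq)
  }
  p_adj <- min(1, m_comparisons * tt$p.value)
  tibble(effect = label, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         p_adjusted = p_adj, correction = "Bonferroni",
         var_equal = veq, levene_p = lev_p, degenerate = FALSE)
}

#' Weekly aggregation of probe-session metrics
#'
#' The chronic study analysed change-from-baseline scores by week, averaging
#' that week's two probe test sessions. Sessions are assigned to consecutive
#' weeks in the order given by `session_levels` (or sorted unique order).
#'
#' @param data Long tibble with a session column and a value column.
#' @param value Name of the value column.
#' @param session Name of the session column.
#' @param subject Name of the subject column.
#' @param sessions_per_week Number of probe sessions per week (default 2).
#' @param session_levels Optional explicit session order.
#' @return Tibble `subject_id`, `week`, `value` (weekly mean).
#' @export
average_by_week <- function(data, value = "value", session = "session_id",
                            subject = "subject_id", sessions_per_week = 2,
                            session_levels = NULL) {
  lv <- session_levels %||% sort(unique(data[[session]]))
  wk <- ceiling(match(data[[session]], lv) / sessions_per_week)
  data %>%
    mutate(week = wk) %>%
    group_by(dplyr::across(dplyr::all_of(subject)), .data$week) %>%
    summarise(value = mean(.data[[value]]), .groups = "drop")
}


# car warns whenever a Huynh-Feldt epsilon exceeds 1; we clip to 1 by
# design, so that warning is expected noise.
quiet_hf <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("HF eps > 1", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
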