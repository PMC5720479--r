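#' Combined signed-RT empirical distribution
#'
#' fast-dm's Kolmogorov-Smirnov construction places both choices on a single
#' axis: low-lever (lower boundary) response times are negated, so the
#' empirical combined distribution is a right-continuous step function with
#' lower-boundary responses occupying the negative half-axis in reversed time
#' order and total mass 1.
#'
#' @param trials A trial tibble (one session) or a tibble with `boundary`
#'   and `rt` columns; omissions/prematures are ignored.
#' @return Tibble with `x` (signed RT, ascending) and `cdf` (step heights).
#' @export
combined_ecdf <- function(trials) {
  x <- signed_rts(trials)
  if (length(x) == 0)
    abort("no lever responses", class = "jbtddm_argument_error")
  x <- sort(x)
  tibble(x = x, cdf = seq_along(x) / length(x))
}

# Signed RTs from either a trial log or a (boundary, rt) tibble.
signed_rts <- function(trials) {
  if ("response" %in% names(trials)) {
    lever <- trials %>%
      filter(.data$response %in% c("high_lever", "low_lever"))
    ifelse(lever$response == "high_lever", lever$rt, -lever$rt)
  } else if (all(c("boundary", "rt") %in% names(trials))) {
    ifelse(trials$boundary == "upper", trials$rt, -trials$rt)
  } else {
    abort("expected trial records or (boundary, rt) draws",
          class = "jbtddm_argument_error")
  }
}

# Parameter bounds used by the penalty (a, zr, v, t0, d, szr, sv, st0)
.fit_lower <- c(a = 0.2, zr = 0.02, v = -10, t0 = 0, d = -2, szr = 0,
                sv = 0, st0 = 0)
.fit_upper <- c(a = 6, zr = 0.98, v = 10, t0 = 19, d = 2, szr = 0.9,
                sv = 3, st0 = 5)

#' Kolmogorov-Smirnov objective
#'
#' The fit criterion: the maximum over tone conditions of the sup-distance
#' between the empirical combined signed-RT distribution and the model's.
#' Parameter sets violating the domain return a finite penalty (greater than
#' any feasible statistic, which lies in [0, 1]) so optimisers can recover.
#'
#' @param trials A probe-session trial tibble; omissions/prematures ignored.
#' @param params_by_tone Named list (`high`, `midpoint`, `low`; any subset)
#'   of [ddm_params()] objects.
#' @return The KS statistic, or a penalty value > 1 for invalid parameters.
#' @export
ks_objective <- function(trials, params_by_tone) {
  tones <- names(params_by_tone)
  xs <- purrr::map(tones, function(tn)
    sort(signed_rts(filter(trials, .data$tone == tn))))
  pars <- do.call(rbind, purrr::map(params_by_tone, as_par_vector))
  ks_eval(xs, pars)
}

ks_eval <- function(xs, pars, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (!feasible_pars(pars)) {
    worst <- which.max(apply(pars, 1, penalty_value))
    return(penalty_value(pars[worst, ]))
  }
  cpp_ks_multi(xs, pars, if (combine == "sum") 1L else 0L)
}

# Vectorised feasibility check over a per-tone parameter matrix
# (columns in .par_fields order).
feasible_pars <- function(pars) {
  if (anyNA(pars) || any(!is.finite(pars))) return(FALSE)
  a <- pars[, 1]; zr <- pars[, 2]; t0 <- pars[, 4]; d <- pars[, 5]
  szr <- pars[, 6]; sv <- pars[, 7]; st0 <- pars[, 8]
  all(a > 0) && all(zr > 0) && all(zr < 1) && all(t0 >= 0) &&
    all(szr >= 0) && all(zr - szr / 2 > 0) && all(zr + szr / 2 < 1) &&
    all(sv >= 0) && all(st0 >= 0) &&
    all(t0 - st0 / 2 - abs(d) / 2 >= -1e-12)
}

# Finite penalty: 1.5 plus the distance to the feasible box, so the
# optimiser has a gradient back towards feasibility.
penalty_value <- function(p) {
  p <- p[.par_fields]
  if (anyNA(p) || any(!is.finite(p))) return(1e3)
  excess <- pmax(0, .fit_lower - p) + pmax(0, p - .fit_upper)
  # structural constraints not captured by the box
  s <- max(0, p[["szr"]] / 2 - min(p[["zr"]], 1 - p[["zr"]])) +
    max(0, p[["st0"]] / 2 + abs(p[["d"]]) / 2 - p[["t0"]])
  1.5 + sum(excess) + s
}

#' Default parameter-sharing specification
#'
#' The stimulus (tone) can only influence processing after it is heard, so
#' drift rate `v` varies by tone while the pre-decisional quantities —
#' boundary separation `a`, relative starting point `zr` and non-decision
#' time `t0` — are session-level. The variability parameters and `d` are
#' fixed at 0 because 120-trial sessions cannot constrain them. Pass a
#' modified spec to [fit_ddm()] to change the sharing (e.g. move `"a"` into
#' `by_tone`).
#'
#' @return A list with components `by_tone`, `shared` and `fixed`.
#' @export
default_fit_spec <- function() {
  list(by_tone = "v", shared = c("a", "zr", "t0"),
       fixed = c(d = 0, szr = 0, sv = 0, st0 = 0))
}

# Heuristic initial values from the data (logistic inversion of the choice
# fractions at a provisional boundary, non-decision time from the fastest RT).
init_theta <- function(xs, spec, layout) {
  all_rt <- abs(unlist(xs))
  t0_init <- 0.85 * min(all_rt)
  a_init <- 1.5
  p_up <- purrr::map_dbl(xs, function(x) {
    n <- length(x)
    if (n == 0) return(0.5)
    (sum(x > 0) + 0.5) / (n + 1)
  })
  v_init <- qlogis(pmin(pmax(p_up, 0.02), 0.98)) / a_init
  defaults <- list(a = rep(a_init, length(xs)), v = v_init,
                   zr = 0.5, t0 = t0_init, d = 0, szr = 0, sv = 0, st0 = 0)
  theta <- numeric(length(layout$names))
  for (i in seq_along(layout$names)) {
    fld <- layout$field[i]
    theta[i] <- if (fld %in% c("a", "v") && layout$tone_idx[i] > 0)
      defaults[[fld]][layout$tone_idx[i]] else defaults[[fld]][1]
  }
  names(theta) <- layout$names
  theta
}

# Build the free-parameter layout for a sharing spec over the tones present.
theta_layout <- function(tones, spec) {
  nms <- character(0); fld <- character(0); idx <- integer(0)
  for (f in spec$by_tone) {
    nms <- c(nms, paste0(f, "_", tones))
    fld <- c(fld, rep(f, length(tones)))
    idx <- c(idx, seq_along(tones))
  }
  for (f in spec$shared) {
    nms <- c(nms, f); fld <- c(fld, f); idx <- c(idx, 0L)
  }
  list(names = nms, field = fld, tone_idx = idx)
}

# Expand a theta vector into the per-tone parameter matrix.
expand_theta <- function(theta, tones, spec, layout) {
  pars <- matrix(NA_real_, nrow = length(tones), ncol = 8,
                 dimnames = list(tones, .par_fields))
  for (f in names(spec$fixed)) pars[, f] <- spec$fixed[[f]]
  for (i in seq_along(layout$names)) {
    f <- layout$field[i]
    if (layout$tone_idx[i] > 0) pars[layout$tone_idx[i], f] <- theta[i]
    else pars[, f] <- theta[i]
  }
  pars
}

#' Fit the diffusion model to one probe session
#'
#' Estimates the diffusion parameters from one probe session's choices and
#' response times by Nelder-Mead from multiple seeded restarts (each
#' followed by a restarted polish pass). Two objectives are available:
#' joint maximum likelihood over tones (`"ml"`, the default — the most
#' efficient estimator at the task's 40 trials per tone) and the fast-dm
#' style Kolmogorov-Smirnov criterion (`"ks"`), which minimises the sum
#' over tones of the combined-distribution sup-distances. Either way the
#' reported `ks_statistic` is the maximum over tones at the optimum, as in
#' [ks_objective()], and serves as the goodness-of-fit value. By default
#' drift rate `v` varies by tone while `a`, `zr` and `t0` are shared across
#' tones within the session, and `d`, `szr`, `sv`, `st0` are fixed at 0;
#' pass `spec` to change the sharing. Omissions and premature responses
#' carry no choice RT and are removed before fitting (counts are kept in
#' the result).
#'
#' @param trials One probe session's trial tibble.
#' @param spec Parameter-sharing spec: list with `by_tone`, `shared`
#'   (character vectors of field names) and `fixed` (named numeric); see
#'   [default_fit_spec()].
#' @param objective `"ml"` (joint maximum likelihood, default) or `"ks"`
#'   (combined-distribution Kolmogorov-Smirnov).
#' @param n_restarts Number of seeded Nelder-Mead restarts (default 5).
#' @param min_trials Minimum lever-responded trials per fitted tone
#'   (default 20).
#' @param seed Integer seed controlling restart jitter.
#' @param maxit Maximum Nelder-Mead iterations per restart.
#' @param reltol Relative convergence tolerance of the simplex (resolves
#'   the KS objective to about 1e-5 at the default).
#' @return An object of class `jbt_fit`: fitted parameters per tone
#'   (`$params`, a tibble), `$ks_statistic`, `$objective`, `$value` (final
#'   objective value), `$converged`, `$n_evaluations`, `$n_trials_used`,
#'   `$removed`, and identifiers.
#' @export
fit_ddm <- function(trials, spec = default_fit_spec(),
                    objective = c("ml", "ks"), n_restarts = 5,
                    min_trials = 20, seed = 1, maxit = 1500,
                    reltol = 1e-6) {
  objective <- match.arg(objective)
  tones <- intersect(.tones, unique(trials$tone))
  lever <- trials %>%
    filter(.data$response %in% c("high_lever", "low_lever"))
  counts <- purrr::map_int(tones, function(tn)
    sum(lever$tone == tn))
  names(counts) <- tones
  if (any(counts < min_trials))
    abort(paste0("insufficient data: fewer than ", min_trials,
                 " responded trials for tone(s) ",
                 paste(tones[counts < min_trials], collapse = ", ")),
          class = "jbtddm_insufficient_data_error")
  removed <- c(
    omission = sum(trials$response == "omission"),
    premature = sum(trials$response == "premature")
  )
  xs <- purrr::map(tones, function(tn)
    sort(signed_rts(filter(lever, .data$tone == tn))))
  layout <- theta_layout(tones, spec)
  theta0 <- init_theta(xs, spec, layout)

  # precomputed assignment indices: theta element -> (row, col) cells
  base_pars <- matrix(NA_real_, nrow = length(tones), ncol = 8,
                      dimnames = list(tones, .par_fields))
  for (f in names(spec$fixed)) base_pars[, f] <- spec$fixed[[f]]
  cells <- do.call(rbind, purrr::map(seq_along(layout$names), function(i) {
    col <- match(layout$field[i], .par_fields)
    rows <- if (layout$tone_idx[i] > 0) layout$tone_idx[i]
            else seq_along(tones)
    cbind(theta = i, row = rows, col = col)
  }))

  obj_fn <- if (objective == "ks") {
    # KS criterion: the SUM of per-tone distances. The reported statistic
    # stays the maximum over tones, but as a search criterion the maximum
    # leaves flat ridges (only the currently worst tone informs the move),
    # which in practice pins the shared starting point at its
    # initialisation; the sum keeps every tone informative.
    function(theta) {
      pars <- base_pars
      pars[cells[, 2:3, drop = FALSE]] <- theta[cells[, 1]]
      ks_eval(xs, pars, combine = "sum")
    }
  } else {
    rt_up <- purrr::map(tones, function(tn)
      lever$rt[lever$tone == tn & lever$response == "high_lever"])
    rt_lo <- purrr::map(tones, function(tn)
      lever$rt[lever$tone == tn & lever$response == "low_lever"])
    function(theta) {
      pars <- base_pars
      pars[cells[, 2:3, drop = FALSE]] <- theta[cells[, 1]]
      if (!feasible_pars(pars)) {
        worst <- which.max(apply(pars, 1, penalty_value))
        return(1e9 * penalty_value(pars[worst, ]))
      }
      cpp_nll_multi(rt_up, rt_lo, pars)
    }
  }

  # restarts explore the starting point systematically: zr is the weakest-
  # identified parameter at task-scale trial counts
  zr_pos <- which(layout$names == "zr")
  best <- NULL
  n_eval <- 0L
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      start <- if (r == 1) theta0 else jitter_theta(theta0, layout)
      if (length(zr_pos) == 1 && r > 1)
        start[zr_pos] <- 0.5 + 0.12 * (r - 1.5) / max(n_restarts - 1.5, 1) *
          (if (r %% 2 == 0) 1 else -1) + stats::rnorm(1, 0, 0.03)
      opt <- optim(start, obj_fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
      # polish pass from the restart's optimum (restarted simplex)
      opt2 <- optim(opt$par, obj_fn, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
      n_eval <- n_eval + opt$counts[["function"]] +
        opt2$counts[["function"]]
      if (opt2$value < opt$value) opt <- opt2
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })
  pars <- expand_theta(best$par, tones, spec, layout)
  converged <- best$convergence == 0 && feasible_pars(pars)
  # the reported goodness-of-fit statistic: max over tones
  ks_stat <- ks_eval(xs, pars, combine = "max")
  params_tbl <- as_tibble(pars) %>% mutate(tone = tones, .before = 1)
  structure(list(
    params = params_tbl,
    shared_params = spec$shared,
    fixed_params = spec$fixed,
    ks_statistic = ks_stat,
    objective = objective,
    value = best$value,
    converged = converged,
    n_evaluations = n_eval,
    n_trials_used = tibble(tone = tones, n = as.integer(counts)),
    removed = removed,
    subject_id = if ("subject_id" %in% names(trials))
      trials$subject_id[1] else NA_character_,
    session_id = if ("session_id" %in% names(trials))
      trials$session_id[1] else NA_character_,
    condition = if ("condition" %in% names(trials))
      trials$condition[1] else NA_character_
  ), class = "jbt_fit")
}

jitter_theta <- function(theta, layout) {
  out <- theta
  for (i in seq_along(theta)) {
    f <- layout$field[i]
    out[i] <- switch(f,
      a = theta[i] * exp(stats::rnorm(1, 0, 0.25)),
      v = theta[i] + stats::rnorm(1, 0, 0.5),
      zr = min(max(theta[i] + stats::rnorm(1, 0, 0.08), 0.05), 0.95),
      t0 = max(theta[i] * stats::runif(1, 0.6, 1.0), 1e-3),
      theta[i] + stats::rnorm(1, 0, 0.05)
    )
  }
  out
}

#' @export
print.jbt_fit <- function(x, ...) {
  cat("<jbt_fit> ", x$subject_id, "/", x$session_id,
      "  KS = ", signif(x$ks_statistic, 4),
      if (!x$converged) "  (not converged)", "\n", sep = "")
  print(as.data.frame(x$params), digits = 4)
  invisible(x)
}

#' Fit every probe session in a cohort
#'
#' Maps [fit_ddm()] over subject x session groups of a trial log and returns
#' one row per subject x session x tone with the fitted parameters and fit
#' diagnostics. Sessions failing the minimum-trial requirement are reported
#' with `converged = NA` rather than aborting the cohort.
#'
#' @inheritParams fit_ddm
#' @param trials A trial tibble covering one or more probe sessions.
#' @return A tibble of fitted parameters.
#' @export
fit_cohort <- function(trials, spec = default_fit_spec(),
                       objective = c("ml", "ks"), n_restarts = 5,
                       min_trials = 20, seed = 1, maxit = 1500,
                       reltol = 1e-6) {
  objective <- match.arg(objective)
  probe <- filter(trials, .data$session_type == "probe")
  keys <- distinct(probe, .data$subject_id, .data$session_id,
                   .data$condition)
  purrr::pmap_dfr(keys, function(subject_id, session_id, condition) {
    one <- filter(probe, .data$subject_id == !!subject_id,
                  .data$session_id == !!session_id)
    fit <- tryCatch(
      fit_ddm(one, spec = spec, objective = objective,
              n_restarts = n_restarts, min_trials = min_trials,
              seed = seed + sum(utf8ToInt(paste0(subject_id, session_id))),
              maxit = maxit, reltol = reltol),
      jbtddm_insufficient_data_error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(subject_id = subject_id, session_id = session_id,
                    condition = condition, tone = NA_character_,
                    converged = NA))
    }
    fit$params %>%
      mutate(subject_id = subject_id, session_id = session_id,
             condition = condition,
             ks_statistic = fit$ks_statistic,
             converged = fit$converged, .before = 1)
  })
}

#' Change from baseline in a fitted parameter
#'
#' Drug-session value minus vehicle-session value of one diffusion parameter
#' for a given tone (default the ambiguous midpoint tone), per the sign
#' convention used for change from baseline in CBI: positive means the
#' parameter increased under drug. A drift rate becoming "less negative"
#' under drug therefore appears as a positive delta.
#'
#' @param fit_drug,fit_vehicle `jbt_fit` objects for the same subject.
#' @param param Parameter name (`"v"`, `"a"`, `"zr"`, ...).
#' @param tone Tone condition (default `"midpoint"`).
#' @return Numeric delta.
#' @export
param_change <- function(fit_drug, fit_vehicle, param = "v",
                         tone = "midpoint") {
  get1 <- function(fit) {
    stopifnot(inherits(fit, "jbt_fit"))
    row <- fit$params[fit$params$tone == tone, ]
    if (nrow(row) != 1 || !param %in% names(row))
      abort(paste0("fit lacks parameter `", param, "` for tone ", tone),
            class = "jbtddm_schema_error")
    row[[param]]
  }
  get1(fit_drug) - get1(fit_vehicle)
}

#' Per-subject parameter changes across a fitted cohort
#'
#' @param fits Output of [fit_cohort()] with `vehicle` and `drug` conditions.
#' @param param Parameter column name.
#' @param tone Tone condition.
#' @return Tibble `subject_id`, `delta`.
#' @export
cohort_param_changes <- function(fits, param = "v", tone = "midpoint") {
  fits %>%
    filter(.data$tone == !!tone) %>%
    rename(value = dplyr::all_of(param)) %>%
    change_from_baseline(value = "value")
}
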