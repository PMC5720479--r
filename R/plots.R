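#' Plot a fitted diffusion model against the data
#'
#' Overlays the model's combined signed-RT distribution function on the
#' empirical step function, one panel per tone — the quantity the
#' Kolmogorov-Smirnov fit actually minimises, so misfit is directly visible.
#'
#' @param object A `jbt_fit`.
#' @param trials The probe-session trial tibble the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jbt_fit <- function(object, trials, ...) {
  tones <- object$params$tone
  emp <- purrr::map_dfr(tones, function(tn) {
    e <- combined_ecdf(filter(trials, .data$tone == tn))
    mutate(e, tone = tn)
  })
  mod <- purrr::map_dfr(tones, function(tn) {
    row <- object$params[object$params$tone == tn, ]
    p <- ddm_params(row$a, row$zr, row$v, row$t0, row$d, row$szr, row$sv,
                    row$st0)
    lim <- max(abs(emp$x[emp$tone == tn])) * 1.2
    x <- seq(-lim, lim, length.out = 200)
    plow <- ddm_absorption(p, "lower")
    f <- ifelse(x < 0, plow - ddm_cdf(p, -x, "lower"),
                plow + ddm_cdf(p, pmax(x, 0), "upper"))
    tibble(x = x, cdf = f, tone = tn)
  })
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$x, y = .data$cdf)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_line(data = mod, colour = "firebrick") +
    ggplot2::facet_wrap(~tone) +
    ggplot2::labs(
      x = "signed RT (s; low-lever responses negative)",
      y = "combined distribution",
      title = sprintf("KS = %.3f", object$ks_statistic)) +
    ggplot2::theme_minimal()
}

#' Plot change-from-baseline scores across a cohort
#'
#' Dot-and-mean display of per-subject deltas (CBI or a fitted parameter),
#' the quantity the one-sample t-tests assess.
#'
#' @param deltas Tibble with `delta` (and optionally `condition`).
#' @param label Y-axis label.
#' @return A ggplot object.
#' @export
plot_change_from_baseline <- function(deltas, label = "change from baseline") {
  df <- mutate(deltas, x = if ("condition" %in% names(deltas))
    .data$condition else "drug")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = label) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
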