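#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted diffusion model
#'
#' One row per tone x parameter, with a flag for parameters shared across
#' tones within the session.
#'
#' @param x A `jbt_fit`.
#' @param ... Unused.
#' @return A tibble with `tone`, `term`, `estimate`, `shared`.
#' @export
tidy.jbt_fit <- function(x, ...) {
  x$params %>%
    tidyr::pivot_longer(-"tone", names_to = "term",
                        values_to = "estimate") %>%
    mutate(shared = .data$term %in% x$shared_params)
}

#' Glance at a fitted diffusion model
#'
#' @param x A `jbt_fit`.
#' @param ... Unused.
#' @return One-row tibble with the KS statistic, convergence flag, optimizer
#'   effort and trial counts.
#' @export
glance.jbt_fit <- function(x, ...) {
  tibble(
    ks_statistic = x$ks_statistic,
    converged = x$converged,
    n_evaluations = x$n_evaluations,
    n_trials = sum(x$n_trials_used$n),
    n_omission = unname(x$removed["omission"]),
    n_premature = unname(x$removed["premature"])
  )
}
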