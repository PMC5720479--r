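#' Drift-diffusion model parameter set
#'
#' Constructs and validates the parameter set of a Wiener diffusion decision
#' process for one subject and condition. Evidence accumulates from a relative
#' starting point `zr` (a fraction of the boundary separation `a`) at drift
#' rate `v` until it is absorbed at the upper boundary (`a`, the high-reward
#' lever) or the lower boundary (0, the low-reward lever). Observed response
#' time is the decision time plus a non-decision time `t0`; `d` is the
#' difference in non-decision time between the two responses (upper response
#' `t0 + d/2`, lower `t0 - d/2`). `szr`, `sv` and `st0` are inter-trial
#' variability parameters: the range of a uniform starting-point jitter, the
#' standard deviation of normal drift variability, and the range of a uniform
#' non-decision-time jitter. The diffusion coefficient is fixed at 1 (fast-dm
#' scaling), so parameter values are only comparable under that convention.
#'
#' @param a Boundary separation, evidence units; `a > 0`.
#' @param zr Relative starting point, in (0, 1).
#' @param v Drift rate, evidence units per second.
#' @param t0 Mean non-decision time, seconds; `t0 >= 0`.
#' @param d Non-decision-time difference between responses, seconds.
#' @param szr Range of uniform starting-point variability (fraction of `a`);
#'   `zr - szr/2` and `zr + szr/2` must stay inside (0, 1).
#' @param sv Standard deviation of normal drift-rate variability; `sv >= 0`.
#' @param st0 Range of uniform non-decision-time variability, seconds;
#'   `t0 - st0/2 - |d|/2` must be non-negative.
#'
#' @return A named numeric vector of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 1.8, zr = 0.5, v = -0.5, t0 = 0.8)
#' ddm_absorption(p, "upper")
#' @export
ddm_params <- function(a, zr, v, t0 = 0, d = 0, szr = 0, sv = 0, st0 = 0) {
  p <- c(a = a, zr = zr, v = v, t0 = t0, d = d, szr = szr, sv = sv, st0 = st0)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

# Field order expected by the C++ routines
.par_fields <- c("a", "zr", "v", "t0", "d", "szr", "sv", "st0")

validate_ddm_params <- function(p) {
  msg <- ddm_params_violation(p)
  if (!is.null(msg)) abort(msg, class = "jbtddm_parameter_domain_error")
  invisible(p)
}

# Returns NULL when valid, otherwise a description of the first violation.
ddm_params_violation <- function(p) {
  p <- unclass(p)[.par_fields]
  if (anyNA(p) || any(!is.finite(p))) return("non-finite parameter value")
  if (p["a"] <= 0) return("boundary separation `a` must be positive")
  if (p["zr"] <= 0 || p["zr"] >= 1) return("relative starting point `zr` must lie in (0, 1)")
  if (p["t0"] < 0) return("non-decision time `t0` must be non-negative")
  if (p["szr"] < 0) return("`szr` must be non-negative")
  if (p["szr"] > 0 &&
      (p["zr"] - p["szr"] / 2 <= 0 || p["zr"] + p["szr"] / 2 >= 1))
    return("starting-point variability range `zr +/- szr/2` leaves (0, 1)")
  if (p["sv"] < 0) return("`sv` must be non-negative")
  if (p["st0"] < 0) return("`st0` must be non-negative")
  if (p["t0"] - p["st0"] / 2 - abs(p["d"]) / 2 < -1e-12)
    return("non-decision time support `t0 - st0/2 - |d|/2` is negative")
  NULL
}

as_par_vector <- function(params) {
  if (inherits(params, "ddm_params")) return(unclass(params)[.par_fields])
  if (is.numeric(params) && all(.par_fields %in% names(params)))
    return(params[.par_fields])
  abort("expected a `ddm_params` object")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>\n")
  print(round(unclass(x), 4))
  invisible(x)
}
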