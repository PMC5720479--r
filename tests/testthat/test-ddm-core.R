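test_that("drift-free absorption probability equals the relative start", {
  expect_equal(ddm_absorption(ddm_params(a = 1, zr = 0.5, v = 0), "upper"),
               0.5)
  expect_equal(ddm_absorption(ddm_params(a = 1, zr = 0.3, v = 0), "upper"),
               0.3)
  # complementarity, with and without variability
  for (p in list(ddm_params(a = 1.3, zr = 0.4, v = 0.7),
                 ddm_params(a = 1.3, zr = 0.4, v = 0.7, t0 = 0.5,
                            szr = 0.2, sv = 0.6, st0 = 0.2))) {
    expect_equal(ddm_absorption(p, "upper") + ddm_absorption(p, "lower"), 1,
                 tolerance = 1e-12)
  }
})

test_that("absorption probability matches a path-simulation oracle", {
  # Independent oracle: Brownian-bridge-corrected Euler-Maruyama with 1e6
  # paths at dt = 1e-4 (v = 1.5, a = 1, zr = 0.5), computed once and frozen.
  # (Naive EM at this step size carries a known discrete-monitoring bias.)
  mc <- 0.817379
  mc_se <- 0.000386
  p <- ddm_absorption(ddm_params(a = 1, zr = 0.5, v = 1.5), "upper")
  expect_lt(abs(p - mc), 3 * mc_se)
})

test_that("absorption probability is strictly monotone in drift and start", {
  pu_v <- sapply(seq(-2, 2, length.out = 9), function(v)
    ddm_absorption(ddm_params(a = 1.2, zr = 0.45, v = v), "upper"))
  expect_true(all(diff(pu_v) > 0))
  pu_z <- sapply(seq(0.1, 0.9, length.out = 9), function(z)
    ddm_absorption(ddm_params(a = 1.2, zr = z, v = 0.4), "upper"))
  expect_true(all(diff(pu_z) > 0))
})

test_that("defective densities conserve total probability on a grid", {
  grid <- expand.grid(a = c(0.8, 1.2, 2), zr = c(0.3, 0.5, 0.7),
                      v = c(-1.5, 0.3, 1))
  for (i in seq_len(nrow(grid))) {
    p <- ddm_params(a = grid$a[i], zr = grid$zr[i], v = grid$v[i])
    total <- stats::integrate(function(t)
      ddm_density(p, t, "upper") + ddm_density(p, t, "lower"),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # and with all variability sources active
  pv <- ddm_params(a = 1.4, zr = 0.45, v = 0.8, t0 = 0.4, d = 0.1,
                   szr = 0.2, sv = 0.7, st0 = 0.2)
  total <- stats::integrate(function(t)
    ddm_density(pv, t, "upper") + ddm_density(pv, t, "lower"),
    0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("reflection symmetry swaps boundaries", {
  tt <- seq(0.02, 4, length.out = 50)
  p1 <- ddm_params(a = 1.3, zr = 0.35, v = 0.9)
  p2 <- ddm_params(a = 1.3, zr = 0.65, v = -0.9)
  expect_equal(ddm_density(p1, tt, "upper"), ddm_density(p2, tt, "lower"),
               tolerance = 1e-12)
  expect_equal(ddm_cdf(p1, tt, "upper"), ddm_cdf(p2, tt, "lower"),
               tolerance = 1e-10)
})

test_that("small-time and large-time series agree where both converge", {
  p <- ddm_params(a = 1, zr = 0.5, v = 1)
  tt <- seq(0.05, 3, length.out = 60)
  for (b in c("upper", "lower")) {
    d_small <- ddm_density(p, tt, b, method = "small")
    d_large <- ddm_density(p, tt, b, method = "large")
    expect_lt(max(abs(d_small - d_large)), 1e-6)
  }
})

test_that("drift-variability density matches a quadrature oracle", {
  # independent route: midpoint-rule mixture of no-variability densities
  # over a fine grid of drifts weighted by the normal density
  p_sv <- ddm_params(a = 1, zr = 0.5, v = 2, sv = 0.8)
  vs <- seq(2 - 6 * 0.8, 2 + 6 * 0.8, length.out = 4001)
  wts <- stats::dnorm(vs, 2, 0.8)
  wts <- wts / sum(wts)
  for (b in c("upper", "lower")) {
    mix <- sum(wts * sapply(vs, function(v)
      ddm_density(ddm_params(a = 1, zr = 0.5, v = v), 0.5, b)))
    expect_equal(ddm_density(p_sv, 0.5, b), mix, tolerance = 1e-4)
  }
})

test_that("CDF starts at zero, is nondecreasing and reaches the absorption mass", {
  p <- ddm_params(a = 1, zr = 0.5, v = 1)
  expect_equal(ddm_cdf(p, 0, "upper"), 0)
  tt <- seq(0, 6, length.out = 100)
  expect_true(all(diff(ddm_cdf(p, tt, "upper")) >= 0))
  expect_equal(ddm_cdf(p, 100, "upper"), ddm_absorption(p, "upper"),
               tolerance = 1e-6)
  # quadrature oracle for an interior value
  quad <- stats::integrate(function(t) ddm_density(p, t, "lower"),
                           0, 0.8, rel.tol = 1e-10)$value
  expect_equal(ddm_cdf(p, 0.8, "lower"), quad, tolerance = 1e-5)
})

test_that("invalid parameters and domains raise typed errors", {
  expect_error(ddm_params(a = -1, zr = 0.5, v = 0),
               class = "jbtddm_parameter_domain_error")
  expect_error(ddm_params(a = 1, zr = 1.2, v = 0),
               class = "jbtddm_parameter_domain_error")
  expect_error(ddm_params(a = 1, zr = 0.5, v = 0, t0 = 0.1, st0 = 0.5),
               class = "jbtddm_parameter_domain_error")
  expect_error(ddm_params(a = 1, zr = 0.9, v = 0, szr = 0.3),
               class = "jbtddm_parameter_domain_error")
  p <- ddm_params(a = 1, zr = 0.5, v = 1)
  expect_error(ddm_density(p, c(0.5, NA)), class = "jbtddm_domain_error")
  expect_error(ddm_cdf(p, Inf), class = "jbtddm_domain_error")
})

test_that("trial simulation is reproducible and respects the RT support", {
  p <- ddm_params(a = 1, zr = 0.5, v = 0.8, t0 = 0.4, d = 0.1, st0 = 0.2)
  set.seed(42); s1 <- ddm_sample(p, 10)
  set.seed(42); s2 <- ddm_sample(p, 10)
  expect_identical(s1, s2)
  expect_error(ddm_sample(p, 0), class = "jbtddm_argument_error")
  set.seed(7); s <- ddm_sample(p, 10000)
  expect_gte(min(s$rt), 0.4 - 0.2 / 2 - 0.1 / 2)
})

test_that("simulated choice fractions obey the absorption probability", {
  p <- ddm_params(a = 1, zr = 0.6, v = 0.5)
  set.seed(11)
  s <- ddm_sample(p, 1e5)
  pu <- ddm_absorption(p, "upper")
  se <- sqrt(pu * (1 - pu) / 1e5)
  expect_lt(abs(mean(s$boundary == "upper") - pu), 3 * se)
})

test_that("simulated RT distributions match the analytic CDF (KS)", {
  p <- ddm_params(a = 1.2, zr = 0.5, v = 1, t0 = 0.3)
  set.seed(3)
  s <- ddm_sample(p, 2e4)
  up <- sort(s$rt[s$boundary == "upper"])
  n <- length(up)
  Fc <- ddm_cdf(p, up, "upper") / ddm_absorption(p, "upper")
  D <- max(pmax(abs(Fc - seq_len(n) / n), abs(Fc - (seq_len(n) - 1) / n)))
  expect_lt(D, 1.628 / sqrt(n))  # alpha = 0.01 critical value
})
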