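// Wiener diffusion first-passage-time machinery.
//
// Conventions (fast-dm scaling): diffusion coefficient fixed at 1; evidence
// starts at zr * a between absorbing boundaries 0 (lower) and a (upper);
// drift v; non-decision time t0 with response-execution difference d
// (upper response: t0 + d/2, lower: t0 - d/2); inter-trial variability:
// zr uniform with range szr, v normal with sd sv, t0 uniform with range st0.

#include <Rcpp.h>
using namespace Rcpp;

static const double EPS_SERIES = 1e-7;   // per-evaluation series truncation

// 10-node Gauss-Legendre on [0, 1]
static const double GL10_X[10] = {
  0.013046735741414128, 0.06746831665550773, 0.16029521585048778,
  0.2833023029353764,   0.4255628305091844,  0.5744371694908156,
  0.7166976970646236,   0.8397047841495122,  0.9325316833444923,
  0.9869532642585859 };
static const double GL10_W[10] = {
  0.03333567215434402, 0.0747256745752903,  0.10954318125799103,
  0.13463335965499817, 0.14776211235737646, 0.14776211235737646,
  0.13463335965499817, 0.10954318125799103, 0.0747256745752903,
  0.03333567215434402 };

// 10-node Gauss-Hermite, rescaled for N(0,1) expectations:
// E[g(Z)] ~ sum_i GH10_W[i] * g(sqrt(2) * GH10_X[i])
static const double GH10_X[10] = {
  -3.436159118837738, -2.5327316742327897, -1.7566836492998816,
  -1.0366108297895136,-0.3429013272237046,  0.3429013272237046,
   1.0366108297895136, 1.7566836492998816,  2.5327316742327897,
   3.436159118837738 };
static const double GH10_W[10] = {
  4.310652630718282e-06, 0.00075807093431224,  0.019111580500770284,
  0.13548370298026705,   0.34464233493201894,  0.34464233493201894,
  0.13548370298026705,   0.019111580500770284, 0.00075807093431224,
  4.310652630718282e-06 };

// P(absorbed at upper boundary | start w*a, drift v), no variability.
static double p_upper_basic(double v, double a, double w) {
  if (v == 0.0) return w;
  double num = -expm1(-2.0 * v * a * w);
  double den = -expm1(-2.0 * v * a);
  return num / den;
}

// Drift-free standardised density f0(tau, w): first passage at the lower
// boundary of a unit-boundary, zero-drift process, scaled time tau = t/a^2.
// f_lower(t | a, v, w) = exp(-v*a*w - v^2 t / 2) * f0(t/a^2, w) / a^2.
// method: 0 = automatic switch, 1 = force small-time, 2 = force large-time.
static double f0_std(double tau, double w, int method) {
  if (tau <= 0.0) return 0.0;
  const double eps = EPS_SERIES;
  // Truncation lengths, chosen analytically per evaluation
  double ks, kl;
  if (2.0 * sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + sqrt(-2.0 * tau * log(2.0 * eps * sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, sqrt(tau) + 1.0);
  } else ks = 2.0;
  if (M_PI * tau * eps < 1.0) {
    kl = sqrt(-2.0 * log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * sqrt(tau)));
  } else kl = 1.0 / (M_PI * sqrt(tau));

  bool small = (method == 1) || (method == 0 && ks < kl);
  if (small) {
    int K = (int)ceil(ks);
    double s = 0.0;
    for (int k = -((K - 1) / 2); k <= (int)ceil((K - 1) / 2.0); ++k) {
      double z = w + 2.0 * k;
      s += z * exp(-z * z / (2.0 * tau));
    }
    return s / sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * exp(-k * k * M_PI * M_PI * tau / 2.0) * sin(k * M_PI * w);
    }
    return M_PI * s;
  }
}

// Density of the decision time at the LOWER boundary, no variability.
static double f_lower_basic(double t, double a, double v, double w,
                            int method = 0) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double tau = t / (a * a);
  double f0 = f0_std(tau, w, method);
  if (f0 <= 0.0) return 0.0;
  return exp(-v * a * w - v * v * t / 2.0) * f0 / (a * a);
}

// Density at the lower boundary with normal drift variability integrated in
// closed form (the drift enters only through exp(-v a w - v^2 t / 2)).
static double f_lower_sv(double t, double a, double v, double w, double sv,
                         int method = 0) {
  if (sv <= 0.0) return f_lower_basic(t, a, v, w, method);
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double tau = t / (a * a);
  double f0 = f0_std(tau, w, method);
  if (f0 <= 0.0) return 0.0;
  double g = 1.0 + sv * sv * t;
  double lfac = (a * a * w * w * sv * sv - 2.0 * a * w * v - v * v * t) /
                (2.0 * g);
  return exp(lfac) / sqrt(g) * f0 / (a * a);
}

// CDF of the decision time at the LOWER boundary, no variability:
// F(t) = P(lower) - (pi/a^2) e^{-v a w} sum_k k sin(k pi w) e^{-lam_k t}/lam_k,
// lam_k = (v^2 + k^2 pi^2 / a^2) / 2, truncated adaptively. Term magnitudes
// are O(1), so the cancellation at small t stays far below the 1e-7
// evaluation tolerance; the result is clamped to [0, P(lower)].
static double F_lower_basic(double t, double a, double v, double w) {
  if (t <= 0.0) return 0.0;
  double plow = 1.0 - p_upper_basic(v, a, w);
  double pref = M_PI / (a * a) * exp(-v * a * w);
  double pi2_a2 = M_PI * M_PI / (a * a);
  double tail = 0.0;
  for (int k = 1; k <= 4000; ++k) {
    double lam = (v * v + k * k * pi2_a2) / 2.0;
    double e = exp(-lam * t);
    tail += k * sin(k * M_PI * w) * e / lam;
    // once the envelope k e^{-lam t} / lam decays it bounds the remainder
    if (k >= 3 && k * e / lam * pref < 1e-10) break;
  }
  double F = plow - pref * tail;
  if (F < 0.0) F = 0.0;
  if (F > plow) F = plow;
  return F;
}

// ---- inter-trial variability wrappers --------------------------------------
// Decision-time density/CDF at a named boundary, integrating over szr
// (Gauss-Legendre) and sv (closed form for the density, Gauss-Hermite for
// the CDF). Upper boundary via the reflection (v, w) -> (-v, 1 - w).

static double dens_decision(double t, bool upper, double a, double zr,
                            double v, double szr, double sv, int method) {
  double vv = upper ? -v : v;
  double w0 = upper ? 1.0 - zr : zr;
  if (szr <= 0.0) return f_lower_sv(t, a, vv, w0, sv, method);
  double s = 0.0;
  for (int i = 0; i < 10; ++i) {
    double w = w0 + szr * (GL10_X[i] - 0.5);
    s += GL10_W[i] * f_lower_sv(t, a, vv, w, sv, method);
  }
  return s;
}

static double cdf_decision(double t, bool upper, double a, double zr,
                           double v, double szr, double sv) {
  double vv = upper ? -v : v;
  double w0 = upper ? 1.0 - zr : zr;
  double s = 0.0;
  int nw = (szr > 0.0) ? 10 : 1;
  int nv = (sv  > 0.0) ? 10 : 1;
  for (int i = 0; i < nw; ++i) {
    double w = (nw == 1) ? w0 : w0 + szr * (GL10_X[i] - 0.5);
    double wi = (nw == 1) ? 1.0 : GL10_W[i];
    for (int j = 0; j < nv; ++j) {
      double vj = (nv == 1) ? vv : vv - sv * M_SQRT2 * GH10_X[j];
      // note: reflected drift for upper is -v; variability is symmetric so
      // applying the normal draw on the reflected scale is equivalent
      double wj = (nv == 1) ? 1.0 : GH10_W[j];
      s += wi * wj * F_lower_basic(t, a, vj, w);
    }
  }
  return s;
}

static double p_boundary_core(bool upper, double a, double zr, double v,
                              double szr, double sv) {
  double s = 0.0;
  int nw = (szr > 0.0) ? 10 : 1;
  int nv = (sv  > 0.0) ? 10 : 1;
  for (int i = 0; i < nw; ++i) {
    double w = (nw == 1) ? zr : zr + szr * (GL10_X[i] - 0.5);
    double wi = (nw == 1) ? 1.0 : GL10_W[i];
    for (int j = 0; j < nv; ++j) {
      double vj = (nv == 1) ? v : v + sv * M_SQRT2 * GH10_X[j];
      double wj = (nv == 1) ? 1.0 : GH10_W[j];
      double pu = p_upper_basic(vj, a, w);
      s += wi * wj * (upper ? pu : 1.0 - pu);
    }
  }
  return s;
}

// Observed-RT density/CDF: shift by the boundary-specific non-decision time
// (t0 +/- d/2) and integrate over its uniform jitter st0.
static double dens_rt(double rt, bool upper, double a, double zr, double v,
                      double t0, double d, double szr, double sv, double st0,
                      int method) {
  double shift = t0 + (upper ? d / 2.0 : -d / 2.0);
  if (st0 <= 0.0)
    return dens_decision(rt - shift, upper, a, zr, v, szr, sv, method);
  double s = 0.0;
  for (int i = 0; i < 10; ++i) {
    double sh = shift + st0 * (GL10_X[i] - 0.5);
    s += GL10_W[i] * dens_decision(rt - sh, upper, a, zr, v, szr, sv, method);
  }
  return s;
}

static double cdf_rt(double rt, bool upper, double a, double zr, double v,
                     double t0, double d, double szr, double sv, double st0) {
  double shift = t0 + (upper ? d / 2.0 : -d / 2.0);
  if (st0 <= 0.0)
    return cdf_decision(rt - shift, upper, a, zr, v, szr, sv);
  double s = 0.0;
  for (int i = 0; i < 10; ++i) {
    double sh = shift + st0 * (GL10_X[i] - 0.5);
    s += GL10_W[i] * cdf_decision(rt - sh, upper, a, zr, v, szr, sv);
  }
  return s;
}

// ---- exported interface ----------------------------------------------------

// [[Rcpp::export]]
double cpp_p_boundary(double a, double zr, double v, double szr, double sv,
                      bool upper) {
  return p_boundary_core(upper, a, zr, v, szr, sv);
}

// [[Rcpp::export]]
NumericVector cpp_density(NumericVector rt, bool upper, double a, double zr,
                          double v, double t0, double d, double szr,
                          double sv, double st0, int method = 0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dens_rt(rt[i], upper, a, zr, v, t0, d, szr, sv, st0, method);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cdf(NumericVector rt, bool upper, double a, double zr,
                      double v, double t0, double d, double szr, double sv,
                      double st0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cdf_rt(rt[i], upper, a, zr, v, t0, d, szr, sv, st0);
  return out;
}

// Exact sampling: realise trial-level (w, v, t0) variability, choose the
// boundary from the absorption probability, then invert the conditional
// decision-time CDF by bisection. Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_sample(int n, double a, double zr, double v, double t0, double d,
                double szr, double sv, double st0) {
  IntegerVector boundary(n);   // 1 = upper, 0 = lower
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    double w = (szr > 0.0) ? zr + szr * (unif_rand() - 0.5) : zr;
    double vi = (sv > 0.0) ? v + sv * norm_rand() : v;
    double pu = p_upper_basic(vi, a, w);
    bool up = unif_rand() < pu;
    // conditional CDF of decision time given the chosen boundary
    double vv = up ? -vi : vi;
    double ww = up ? 1.0 - w : w;
    double pb = up ? pu : 1.0 - pu;
    double u = unif_rand() * pb;
    double hi = a * a;  // initial bracket on the scaled-time scale
    int guard = 0;
    while (F_lower_basic(hi, a, vv, ww) < u && guard++ < 60) hi *= 2.0;
    double lo = 0.0;
    for (int it = 0; it < 60; ++it) {
      double mid = 0.5 * (lo + hi);
      if (F_lower_basic(mid, a, vv, ww) < u) lo = mid; else hi = mid;
    }
    double tdec = 0.5 * (lo + hi);
    double shift = t0 + (up ? d / 2.0 : -d / 2.0);
    if (st0 > 0.0) shift += st0 * (unif_rand() - 0.5);
    boundary[i] = up ? 1 : 0;
    rt[i] = tdec + shift;
  }
  return List::create(_["boundary"] = boundary, _["rt"] = rt);
}

// Kolmogorov-Smirnov distance between the empirical combined (signed-RT)
// distribution and the model's, fast-dm style: lower-boundary responses at
// -RT, upper at +RT. x must be sorted ascending. par = (a, zr, v, t0, d,
// szr, sv, st0).
// [[Rcpp::export]]
double cpp_ks_stat(NumericVector x, NumericVector par) {
  int n = x.size();
  double a = par[0], zr = par[1], v = par[2], t0 = par[3], d = par[4],
         szr = par[5], sv = par[6], st0 = par[7];
  double plow = p_boundary_core(false, a, zr, v, szr, sv);
  double D = 0.0;
  for (int i = 0; i < n; ++i) {
    double Fm;
    if (x[i] < 0.0)
      Fm = plow - cdf_rt(-x[i], false, a, zr, v, t0, d, szr, sv, st0);
    else
      Fm = plow + cdf_rt(x[i], true, a, zr, v, t0, d, szr, sv, st0);
    double lo = (double)i / n, hi = (double)(i + 1) / n;
    D = std::max(D, std::max(fabs(Fm - lo), fabs(Fm - hi)));
  }
  return D;
}

// Joint negative log-likelihood over tone conditions. up/lo: per-condition
// vectors of observed RTs ending at the upper/lower boundary; pars as in
// cpp_ks_multi. RTs with non-positive model density (e.g. below the
// candidate non-decision time) make the value a large finite penalty that
// grows with the number of violating trials, so the optimiser can recover.
// [[Rcpp::export]]
double cpp_nll_multi(List up, List lo, NumericMatrix pars) {
  double s = 0.0;
  int bad = 0;
  for (int j = 0; j < up.size(); ++j) {
    NumericVector par = pars(j, _);
    double a = par[0], zr = par[1], v = par[2], t0 = par[3], d = par[4],
           szr = par[5], sv = par[6], st0 = par[7];
    NumericVector ru = up[j], rl = lo[j];
    for (int i = 0; i < ru.size(); ++i) {
      double f = dens_rt(ru[i], true, a, zr, v, t0, d, szr, sv, st0, 0);
      if (f > 0.0 && R_finite(f)) s -= log(f); else ++bad;
    }
    for (int i = 0; i < rl.size(); ++i) {
      double f = dens_rt(rl[i], false, a, zr, v, t0, d, szr, sv, st0, 0);
      if (f > 0.0 && R_finite(f)) s -= log(f); else ++bad;
    }
  }
  if (bad > 0) return 1e9 + 1e3 * bad;
  return s;
}

// KS distances combined over tone conditions. xs: list of sorted signed-RT
// vectors; pars: one row per condition, columns (a, zr, v, t0, d, szr, sv,
// st0). combine: 0 = maximum over conditions (the reported statistic),
// 1 = sum over conditions (the fitting criterion, which keeps every
// condition informative instead of only the currently worst one).
// [[Rcpp::export]]
double cpp_ks_multi(List xs, NumericMatrix pars, int combine = 0) {
  double D = 0.0;
  for (int j = 0; j < xs.size(); ++j) {
    NumericVector x = xs[j];
    if (x.size() == 0) continue;
    NumericVector par = pars(j, _);
    double d = cpp_ks_stat(x, par);
    D = combine == 1 ? D + d : std::max(D, d);
  }
  return D;
}
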