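// Binomial-logit-normal likelihood core.
//
// The per-individual marginal log-probability integrates the binomial
// likelihood against the latent Normal(0, sigma^2) log allelic fold change
// with Gauss-Hermite quadrature recentred at the mode of the integrand
// (Liu-Pierce adaptive rule), so modest orders stay accurate for totals up
// to ~1e5 and sigma up to several log units.  The 1-D profile over sigma is
// maximized with Brent's method on log(sigma).

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
#include <vector>

using namespace Rcpp;

// Brent's derivative-free 1-D minimizer on [ax, bx] (Brent 1973, localmin).
static double brent_fmin(double ax, double bx,
                         double (*f)(double, void*), void* info,
                         double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(DBL_EPSILON);
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  for (int iter = 0; iter < 200; ++iter) {
    const double xm = 0.5 * (a + b);
    const double tol1 = eps * std::fabs(x) + tol / 3.0;
    const double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool golden = true;
    if (std::fabs(e) > tol1) {  // try parabolic interpolation
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      const double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        const double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x < xm) ? b - x : a - x;
      d = c * e;
    }
    const double u = (std::fabs(d) >= tol1) ? x + d
                                            : x + ((d > 0) ? tol1 : -tol1);
    const double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

static const double HALF_LOG_2PI = 0.91893853320467274178;

// log(plogis(d)) stable in both tails
static inline double log_plogis(double d) {
  return d > 0 ? -log1p(std::exp(-d)) : d - log1p(std::exp(d));
}

// log Pr(X = x | n, sigma) with mu = 0, adaptive Gauss-Hermite.
static double bln_logpmf_one(double x, double n, double sigma,
                             const double* t, const double* logw, int Q) {
  if (n == 0.0) return 0.0;
  if (sigma <= 0.0) return R::dbinom(x, n, 0.5, 1);
  const double tau2 = sigma * sigma;
  const double pt = (x + 0.5) / (n + 1.0);
  const double w2 = 1.0 / (n * pt * (1.0 - pt));
  double delta = std::log(pt / (1.0 - pt)) * tau2 / (tau2 + w2);
  for (int it = 0; it < 10; ++it) {
    const double p = 1.0 / (1.0 + std::exp(-delta));
    const double step = (x - n * p - delta / tau2) /
                        (n * p * (1.0 - p) + 1.0 / tau2);
    delta += step;
    if (std::fabs(step) < 1e-10) break;
  }
  const double p = 1.0 / (1.0 + std::exp(-delta));
  const double s = 1.0 / std::sqrt(n * p * (1.0 - p) + 1.0 / tau2);
  const double lc = R::lchoose(n, x);
  const double lsig = std::log(sigma);
  std::vector<double> v(Q);
  double vmax = R_NegInf;
  for (int k = 0; k < Q; ++k) {
    const double d = delta + M_SQRT2 * s * t[k];
    const double lp = log_plogis(d);
    const double h = lc + x * lp + (n - x) * (lp - d) -
                     0.5 * d * d / tau2 - lsig - HALF_LOG_2PI;
    v[k] = logw[k] + t[k] * t[k] + h;
    if (v[k] > vmax) vmax = v[k];
  }
  double acc = 0.0;
  for (int k = 0; k < Q; ++k) acc += std::exp(v[k] - vmax);
  return 0.5 * M_LN2 + std::log(s) + vmax + std::log(acc);
}

struct LikData {
  const double* a;
  const double* n;
  int m;
  const double* t;
  const double* logw;
  int Q;
};

static double negloglik(double logsigma, void* info) {
  LikData* d = static_cast<LikData*>(info);
  const double sigma = std::exp(logsigma);
  double ll = 0.0;
  for (int i = 0; i < d->m; ++i)
    ll += bln_logpmf_one(d->a[i], d->n[i], sigma, d->t, d->logw, d->Q);
  return -ll;
}

// [[Rcpp::export]]
double bln_loglik_cpp(NumericVector a, NumericVector n, double sigma,
                      NumericVector t, NumericVector logw) {
  LikData d = {a.begin(), n.begin(), (int)a.size(),
               t.begin(), logw.begin(), (int)t.size()};
  return -negloglik(std::log(sigma), &d);
}

// Maximize the BLN profile likelihood over sigma in [lo, hi] (Brent on
// log sigma).  Returns sigma, loglik, and a boundary flag.
// [[Rcpp::export]]
List bln_fit_sigma_cpp(NumericVector a, NumericVector n,
                       double lo, double hi,
                       NumericVector t, NumericVector logw,
                       double tol = 1e-5) {
  LikData d = {a.begin(), n.begin(), (int)a.size(),
               t.begin(), logw.begin(), (int)t.size()};
  const double llo = std::log(lo), lhi = std::log(hi);
  const double ls = brent_fmin(llo, lhi, negloglik, &d, tol);
  double sigma = std::exp(ls);
  double nll = negloglik(ls, &d);
  // Brent never evaluates the endpoints; check them explicitly.
  const double nll_lo = negloglik(llo, &d);
  const double nll_hi = negloglik(lhi, &d);
  bool at_lo = false, at_hi = false;
  if (nll_lo <= nll) { sigma = lo; nll = nll_lo; }
  if (nll_hi <  nll) { sigma = hi; nll = nll_hi; }
  if (std::log(sigma) - llo < 2.0 * tol) { at_lo = true; sigma = lo; nll = nll_lo; }
  if (lhi - std::log(sigma) < 2.0 * tol) { at_hi = true; sigma = hi; nll = nll_hi; }
  return List::create(_["sigma"] = sigma,
                      _["loglik"] = -nll,
                      _["at_lower"] = at_lo,
                      _["at_upper"] = at_hi);
}

// Parametric bootstrap: resample haplotype counts conditional on the observed
// totals under sigma_hat, refit, return the B resampled sigma estimates.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector bln_bootstrap_cpp(NumericVector n, double sigma_hat, int B,
                                double lo, double hi,
                                NumericVector t, NumericVector logw,
                                double tol = 1e-4) {
  RNGScope scope;
  const int m = n.size();
  NumericVector out(B);
  std::vector<double> astar(m);
  LikData d = {astar.data(), n.begin(), m, t.begin(), logw.begin(),
               (int)t.size()};
  const double llo = std::log(lo), lhi = std::log(hi);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < m; ++i) {
      const double delta = R::rnorm(0.0, sigma_hat);
      const double p = 1.0 / (1.0 + std::exp(-delta));
      astar[i] = R::rbinom(n[i], p);
    }
    const double ls = brent_fmin(llo, lhi, negloglik, &d, tol);
    double sigma = std::exp(ls);
    const double nll = negloglik(ls, &d);
    if (negloglik(llo, &d) <= nll) sigma = lo;
    else if (negloglik(lhi, &d) < nll) sigma = hi;
    out[b] = sigma;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
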