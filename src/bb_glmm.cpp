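// Laplace-approximated marginal negative log-likelihood of the per-locus
// beta-binomial GLMM. Hot path of the genome scan: called thousands of
// times per locus by the outer quasi-Newton optimizer.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampp(double p) {
  if (p < 1e-9) return 1e-9;
  if (p > 1.0 - 1e-9) return 1.0 - 1e-9;
  return p;
}

// log beta-binomial pmf, intra-class correlation parameterization
static inline double bb_lpmf(double y, double n, double p, double cc) {
  double a = p * cc, b = (1.0 - p) * cc;
  return R::lchoose(n, y) + R::lbeta(y + a, n - y + b) - R::lbeta(a, b);
}

// [[Rcpp::export(name = ".bb_nll_laplace")]]
List bb_nll_laplace(NumericVector par, NumericVector y, NumericVector n,
                    NumericMatrix X, IntegerVector ji, int J,
                    NumericVector u_start) {
  const int m = y.size();
  double beta0 = par[0], beta1 = par[1], beta2 = par[2], beta3 = par[3];
  double phi = 1.0 / (1.0 + std::exp(-par[4]));
  double sig2 = std::exp(2.0 * par[5]);
  double cc = (1.0 - phi) / phi;

  std::vector<double> eta0(m);
  for (int i = 0; i < m; ++i)
    eta0[i] = beta0 * X(i, 0) + beta1 * X(i, 1) + beta2 * X(i, 2) +
      beta3 * X(i, 3);

  std::vector<double> u(J, 0.0);
  if (u_start.size() == J)
    for (int j = 0; j < J; ++j) u[j] = u_start[j];

  std::vector<double> g1(J), g2(J);
  for (int it = 0; it < 25; ++it) {
    std::fill(g1.begin(), g1.end(), 0.0);
    std::fill(g2.begin(), g2.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      int j = ji[i] - 1;
      double p = clampp(1.0 / (1.0 + std::exp(-(eta0[i] + u[j]))));
      double a = p * cc, b = (1.0 - p) * cc;
      double d1p = cc * (R::digamma(y[i] + a) - R::digamma(a) -
                         R::digamma(n[i] - y[i] + b) + R::digamma(b));
      double d2p = cc * cc * (R::trigamma(y[i] + a) - R::trigamma(a) +
                              R::trigamma(n[i] - y[i] + b) - R::trigamma(b));
      double w = p * (1.0 - p);
      g1[j] += d1p * w;
      g2[j] += d2p * w * w + d1p * w * (1.0 - 2.0 * p);
    }
    double maxstep = 0.0;
    for (int j = 0; j < J; ++j) {
      double gg1 = g1[j] - u[j] / sig2;
      double gg2 = g2[j] - 1.0 / sig2;
      if (gg2 > -1e-8) gg2 = -1e-8;
      double step = -gg1 / gg2;
      if (step > 3.0) step = 3.0;
      if (step < -3.0) step = -3.0;
      u[j] += step;
      if (std::fabs(step) > maxstep) maxstep = std::fabs(step);
    }
    if (maxstep < 1e-7) break;
  }

  // value and curvature at the modes
  std::vector<double> llj(J, 0.0);
  std::fill(g2.begin(), g2.end(), 0.0);
  for (int i = 0; i < m; ++i) {
    int j = ji[i] - 1;
    double p = clampp(1.0 / (1.0 + std::exp(-(eta0[i] + u[j]))));
    llj[j] += bb_lpmf(y[i], n[i], p, cc);
    double a = p * cc, b = (1.0 - p) * cc;
    double d1p = cc * (R::digamma(y[i] + a) - R::digamma(a) -
                       R::digamma(n[i] - y[i] + b) + R::digamma(b));
    double d2p = cc * cc * (R::trigamma(y[i] + a) - R::trigamma(a) +
                            R::trigamma(n[i] - y[i] + b) - R::trigamma(b));
    double w = p * (1.0 - p);
    g2[j] += d2p * w * w + d1p * w * (1.0 - 2.0 * p);
  }
  double nll = 0.0;
  for (int j = 0; j < J; ++j) {
    double H = -(g2[j] - 1.0 / sig2);
    if (H < 1e-10) H = 1e-10;
    nll -= llj[j] - u[j] * u[j] / (2.0 * sig2) - 0.5 * std::log(sig2) -
      0.5 * std::log(H);
  }
  if (!std::isfinite(nll)) nll = 1e10;
  return List::create(_["value"] = nll,
                      _["u"] = NumericVector(u.begin(), u.end()));
}
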