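#include <Rcpp.h>
using namespace Rcpp;

// Standard-normal tail areas via erfc; accurate to ~1 ulp and considerably
// faster than going through R's pnorm in a tight loop.
static inline double norm_cdf_lower(double x, double mean, double sd) {
  return 0.5 * std::erfc(-(x - mean) / (sd * M_SQRT2));
}
static inline double norm_cdf_upper(double x, double mean, double sd) {
  return 0.5 * std::erfc((x - mean) / (sd * M_SQRT2));
}

// Gaussian probability of the bin [lo, hi), computed two-sided: below the
// mean the lower-tail CDFs are differenced, above it the upper-tail CDFs.
// A one-sided difference underflows to exactly zero (1 - 1 in doubles) a
// few sd into the opposite tail, which would grossly overstate log-ratios
// once the mass floor is applied.
static inline double bin_mass(double lo, double hi, double m, double s) {
  double a;
  if (hi <= m) {
    a = norm_cdf_lower(hi, m, s) - norm_cdf_lower(lo, m, s);
  } else if (lo >= m) {
    a = norm_cdf_upper(lo, m, s) - norm_cdf_upper(hi, m, s);
  } else {
    a = 1.0 - norm_cdf_lower(lo, m, s) - norm_cdf_upper(hi, m, s);
  }
  return (a < 1e-300) ? 1e-300 : a;
}

// KL divergence between the discretized belief Normal(m1, v1) and the
// discretized belief Normal(m2, v2) on the integer grid lower..upper, with
// bins [i - 0.5, i + 0.5) truncated to the grid support, masses floored at
// 1e-300 and renormalized — the same construction as discretize() in R.
static double kl_discrete(double m1, double v1, double m2, double v2,
                          double lower, int n) {
  const double s1 = std::sqrt(v1), s2 = std::sqrt(v2);
  std::vector<double> pp(n), qq(n);
  double sum_p = 0.0, sum_q = 0.0;
  for (int i = 0; i < n; ++i) {
    const double lo = lower + i - 0.5;
    const double hi = lo + 1.0;
    pp[i] = bin_mass(lo, hi, m1, s1);
    qq[i] = bin_mass(lo, hi, m2, s2);
    sum_p += pp[i];
    sum_q += qq[i];
  }
  double kl = 0.0;
  for (int i = 0; i < n; ++i) {
    const double p = pp[i] / sum_p;
    const double q = qq[i] / sum_q;
    kl += p * std::log(p / q);
  }
  return kl;
}

// Per-trial KL divergence between the discretized individual belief
// Normal(J1, tau2) and the discretized fused posterior.
// [[Rcpp::export(name = ".kl_bayes_core")]]
NumericVector kl_bayes_core(NumericVector J1, NumericVector tau2,
                            NumericVector JS, NumericVector sig2,
                            double lower, double upper) {
  const int t = J1.size();
  if (tau2.size() != t || JS.size() != t || sig2.size() != t)
    stop("trial vectors must have equal length");
  const int n = (int)(upper - lower) + 1;
  NumericVector out(t);
  for (int k = 0; k < t; ++k) {
    if (!(tau2[k] > 0.0) || !(sig2[k] > 0.0))
      stop("variances must be positive");
    const double pm =
        (tau2[k] * JS[k] + sig2[k] * J1[k]) / (sig2[k] + tau2[k]);
    const double pv = sig2[k] * tau2[k] / (sig2[k] + tau2[k]);
    out[k] = kl_discrete(J1[k], tau2[k], pm, pv, lower, n);
  }
  return out;
}

// Full Bayesian-model deviance for one parameter vector: per-trial KL
// predictions signed by the judgment-gap direction, scale eta and error
// variance eps2 profiled in closed form, Gaussian -2 log likelihood.
// This is the optimizer's objective; it must agree with the composed R
// path (predict_change_bayes + profile_scale + neg2_log_likelihood).
// [[Rcpp::export(name = ".bayes_neg2ll_core")]]
double bayes_neg2ll_core(double beta_C, double omega_C,
                         double sigma5, double sigma20,
                         NumericVector J1, NumericVector C,
                         NumericVector JS, NumericVector G,
                         NumericVector obs, double eps2_floor) {
  const int t = J1.size();
  if (C.size() != t || JS.size() != t || G.size() != t || obs.size() != t)
    stop("trial vectors must have equal length");
  const double s5sq = sigma5 * sigma5, s20sq = sigma20 * sigma20;
  const int n = 31;
  std::vector<double> pred(t);
  for (int k = 0; k < t; ++k) {
    const double prec = beta_C + omega_C * C[k];
    if (!(prec > 0.0)) stop("nonpositive precision in objective");
    const double tau2 = 1.0 / prec;
    const double sig2 = (G[k] == 1.0) ? s20sq : s5sq;
    const double pm = (tau2 * JS[k] + sig2 * J1[k]) / (sig2 + tau2);
    const double pv = sig2 * tau2 / (sig2 + tau2);
    const double kl = kl_discrete(J1[k], tau2, pm, pv, 0.0, n);
    pred[k] = (JS[k] > J1[k]) ? kl : ((JS[k] < J1[k]) ? -kl : 0.0);
  }
  double ss = 0.0, sp = 0.0;
  for (int k = 0; k < t; ++k) {
    ss += pred[k] * pred[k];
    sp += pred[k] * obs[k];
  }
  double eta, rss = 0.0;
  if (ss == 0.0) {
    eta = 0.0;
    for (int k = 0; k < t; ++k) rss += obs[k] * obs[k];
  } else {
    eta = sp / ss;
    for (int k = 0; k < t; ++k) {
      const double r = obs[k] - eta * pred[k];
      rss += r * r;
    }
  }
  double eps2 = rss / t;
  if (eps2 < eps2_floor) eps2 = eps2_floor;
  return t * std::log(2.0 * M_PI * eps2) + rss / eps2;
}
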