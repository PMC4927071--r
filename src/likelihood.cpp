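// Analytic TCSPC bin-likelihood kernels.
//
// The decay signal is a mixture of exponentials convolved with a weighted
// mixture of truncated Gaussians (the instrument response), observed on a
// periodic excitation window. All bin probabilities reduce to differences of
// the antiderivative kernel chi(tau, t, sigma, delta, u):
//
//   chi = erf((t-u)/(sigma sqrt2))
//       + e^{-(t-u)/tau + sigma^2/2tau^2} [erf(q(t)) - erf(q(delta))],
//   q(x) = (u-x)/(sigma sqrt2) + sigma/(tau sqrt2).
//
// The exponential prefactor can overflow while the erf bracket cancels to
// ~e^{-q^2}; each product e^E erf(q) is therefore evaluated through the
// scaled complementary error function using the identity
//   E - q(x)^2 = -(u-x)^2/(2 sigma^2) + (x-t)/tau,
// which keeps every retained term damped. A bare e^E survives only when
// q(t) and q(delta) differ in sign, in which case t > u + sigma^2/tau and
// E < sigma^2/(2 tau^2); this is finite for all sane sigma/tau ratios and
// callers guard non-finite values.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT2 = 0.70710678118654752440;
static const double SQRT_PI = 1.77245385090551602730;

// erfcx(x) = exp(x^2) erfc(x), for x >= 0 only.
static inline double erfcx_pos(double x) {
  if (x < 25.0) return std::exp(x * x) * std::erfc(x);
  double s = 1.0 / (x * x);
  // asymptotic expansion, relative error < 1e-12 for x >= 25
  return (1.0 - 0.5 * s * (1.0 - 1.5 * s * (1.0 - 2.5 * s * (1.0 - 3.5 * s)))) /
         (x * SQRT_PI);
}

static double chi_scalar(double tau, double t, double sigma, double delta,
                         double u) {
  const double inv_s = INV_SQRT2 / sigma;           // 1/(sigma sqrt2)
  const double a = sigma * INV_SQRT2 / tau;         // sigma/(tau sqrt2)
  const double erf1 = std::erf((t - u) * inv_s);
  const double qt = (u - t) * inv_s + a;
  const double qd = (u - delta) * inv_s + a;
  const double st = (qt > 0.0) ? 1.0 : ((qt < 0.0) ? -1.0 : 0.0);
  const double sd = (qd > 0.0) ? 1.0 : ((qd < 0.0) ? -1.0 : 0.0);
  const double lg_t = -0.5 * (u - t) * (u - t) / (sigma * sigma);
  const double lg_d =
      -0.5 * (u - delta) * (u - delta) / (sigma * sigma) + (delta - t) / tau;
  double val = erf1;
  const double sdiff = st - sd;
  if (sdiff != 0.0) {
    const double E = -(t - u) / tau + 0.5 * sigma * sigma / (tau * tau);
    val += sdiff * std::exp(E);
  }
  if (st != 0.0) val -= st * erfcx_pos(std::fabs(qt)) * std::exp(lg_t);
  if (sd != 0.0) val += sd * erfcx_pos(std::fabs(qd)) * std::exp(lg_d);
  return val;
}

// Integral of the (un-normalised) decay-IRF convolution over [tL, tH] for one
// truncated-Gaussian component; zero below the cutoff, from the cutoff for a
// straddling interval, full difference above.
static inline double psi_scalar(double tau, double tL, double tH, double sigma,
                                double delta, double u) {
  if (tH <= delta || tH <= tL) return 0.0;
  double hi = chi_scalar(tau, tH, sigma, delta, u);
  double lo = (tL > delta) ? chi_scalar(tau, tL, sigma, delta, u)
                           : chi_scalar(tau, delta, sigma, delta, u);
  return hi - lo;
}

// [[Rcpp::export]]
NumericVector cpp_chi(double tau, NumericVector t, double sigma, double delta,
                      double u) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = chi_scalar(tau, t[i], sigma, delta, u);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_psi(double tau, NumericVector t_lower, NumericVector t_upper,
                      double sigma, double delta, double u) {
  int n = t_lower.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = psi_scalar(tau, t_lower[i], t_upper[i], sigma, delta, u);
  return out;
}

// Un-normalised fluorescence mass per bin for one lifetime, summed over the
// excitation history l = 0..ell_max and all IRF components. gamma_t are the
// truncation-corrected weights gamma_i / (1 + erf((u_i - delta_i)/sigma_i
// sqrt2)). Adjacent bins share chi evaluations at their common edge.
static void fluor_accumulate(double tau, const NumericVector &edges,
                             const NumericVector &gamma_t,
                             const NumericVector &center,
                             const NumericVector &width,
                             const NumericVector &cutoff, double period,
                             int ell_max, std::vector<double> &out) {
  const int M = edges.size() - 1;
  const int I = gamma_t.size();
  std::vector<double> ce(M + 1);
  for (int i = 0; i < I; ++i) {
    const double s = width[i], d = cutoff[i], u = center[i], g = gamma_t[i];
    const double chid = chi_scalar(tau, d, s, d, u);
    for (int l = 0; l <= ell_max; ++l) {
      const double off = l * period;
      for (int j = 0; j <= M; ++j) {
        double t = off + edges[j];
        ce[j] = (t >= d) ? chi_scalar(tau, t, s, d, u) : 0.0;
      }
      for (int j = 0; j < M; ++j) {
        const double tL = off + edges[j], tH = off + edges[j + 1];
        if (tH <= d) continue;
        const double lo = (tL > d) ? ce[j] : chid;
        out[j] += g * (ce[j + 1] - lo);
      }
    }
  }
}

static double fluor_norm(double tau, const NumericVector &gamma_t,
                         const NumericVector &center,
                         const NumericVector &width,
                         const NumericVector &cutoff, double period,
                         double window, int ell_max) {
  double lambda = 0.0;
  for (int i = 0; i < gamma_t.size(); ++i)
    for (int l = 0; l <= ell_max; ++l)
      lambda += gamma_t[i] * psi_scalar(tau, l * period, l * period + window,
                                        width[i], cutoff[i], center[i]);
  return lambda;
}

// [[Rcpp::export]]
NumericVector cpp_fluor_bin_probs(double tau, NumericVector edges,
                                  NumericVector gamma_t, NumericVector center,
                                  NumericVector width, NumericVector cutoff,
                                  double period, double window, int ell_max,
                                  bool normalize) {
  const int M = edges.size() - 1;
  std::vector<double> acc(M, 0.0);
  fluor_accumulate(tau, edges, gamma_t, center, width, cutoff, period, ell_max,
                   acc);
  NumericVector out(M);
  double lambda = 1.0;
  if (normalize)
    lambda = fluor_norm(tau, gamma_t, center, width, cutoff, period, window,
                        ell_max);
  for (int j = 0; j < M; ++j) out[j] = acc[j] / lambda;
  return out;
}

// Per-l decomposition of the normalised fluorescence bin likelihood (rows:
// l = 0..ell_max), used to examine the wrap-around "pre-rise" contribution.
// [[Rcpp::export]]
NumericMatrix cpp_fluor_bin_terms(double tau, NumericVector edges,
                                  NumericVector gamma_t, NumericVector center,
                                  NumericVector width, NumericVector cutoff,
                                  double period, double window, int ell_max) {
  const int M = edges.size() - 1;
  NumericMatrix out(ell_max + 1, M);
  const double lambda =
      fluor_norm(tau, gamma_t, center, width, cutoff, period, window, ell_max);
  for (int l = 0; l <= ell_max; ++l) {
    for (int j = 0; j < M; ++j) {
      double v = 0.0;
      for (int i = 0; i < gamma_t.size(); ++i)
        v += gamma_t[i] * psi_scalar(tau, l * period + edges[j],
                                     l * period + edges[j + 1], width[i],
                                     cutoff[i], center[i]);
      out(l, j) = v / lambda;
    }
  }
  return out;
}

// Full photon bin probabilities p(b) = |b| w0 / T + sum_k w_k F(tau_k, b).
// [[Rcpp::export]]
NumericVector cpp_photon_bin_probs(NumericVector lifetimes,
                                   NumericVector weights, double background,
                                   NumericVector edges, NumericVector gamma_t,
                                   NumericVector center, NumericVector width,
                                   NumericVector cutoff, double period,
                                   double window, int ell_max) {
  const int M = edges.size() - 1;
  NumericVector out(M);
  for (int j = 0; j < M; ++j)
    out[j] = background * (edges[j + 1] - edges[j]) / window;
  for (int k = 0; k < lifetimes.size(); ++k) {
    std::vector<double> acc(M, 0.0);
    fluor_accumulate(lifetimes[k], edges, gamma_t, center, width, cutoff,
                     period, ell_max, acc);
    const double lambda = fluor_norm(lifetimes[k], gamma_t, center, width,
                                     cutoff, period, window, ell_max);
    for (int j = 0; j < M; ++j) out[j] += weights[k] * acc[j] / lambda;
  }
  return out;
}
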