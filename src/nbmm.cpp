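#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Negative marginal log-likelihood of the NB mixed model with a subject
// random intercept, integrated per subject by adaptive Gauss-Hermite
// quadrature. Cells must be sorted by subject; subj_start holds the 0-based
// start offset of each subject's cell block (length J + 1).
//
// par = (beta[0..p-1], sigma if sigma_free, sqrt_phi). The standard
// deviation sigma and sqrt(phi) are parametrized on their natural scale so
// that null variance components sit at a clean lower bound of 0 instead of
// being approached along an asymptote.
//
// The NB log-density splits into a node-independent part (gamma terms and
// y * eta, accumulated once per subject; the gamma terms are cached over
// the distinct count values, which are few for sparse panels) and a
// node-dependent part that costs a single log1p per (cell, node):
//   ll(y | eta + t) = const(y, k) + y (eta - log k)
//                     + t y - (y + k) log1p(mu0 e^t / k),  mu0 = exp(eta).
//
// u_init carries warm-start values for the per-subject conditional modes;
// the updated modes are returned so successive likelihood evaluations
// start their Newton search near the solution.
// [[Rcpp::export]]
List nbmm_nll_cpp(NumericVector par, NumericMatrix X, NumericVector y,
                  NumericVector offset, IntegerVector subj_start,
                  NumericVector z, NumericVector w,
                  bool sigma_free, double sigma2_fixed,
                  NumericVector u_init) {
  const int n = y.size();
  const int p = X.ncol();
  const int J = subj_start.size() - 1;
  const int Q = z.size();

  double sigma = sigma_free ? std::fabs(par[p]) : std::sqrt(sigma2_fixed);
  double sqrt_phi = std::fabs(par[p + (sigma_free ? 1 : 0)]);
  const double phi = sqrt_phi * sqrt_phi;
  const bool poisson = phi < 1e-8;
  const double k = poisson ? 0.0 : 1.0 / phi;
  const double logk = poisson ? 0.0 : std::log(k);
  const double sigma2 = sigma * sigma;

  std::vector<double> eta(n), mu0(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i];
    for (int j = 0; j < p; ++j) e += X(i, j) * par[j];
    eta[i] = e;
    mu0[i] = std::exp(e);
  }

  // parameter-dependent gamma constants, cached over distinct counts
  std::unordered_map<double, double> cst_cache;
  cst_cache.reserve(64);
  auto cst = [&](double yi) -> double {
    auto it = cst_cache.find(yi);
    if (it != cst_cache.end()) return it->second;
    double v = poisson ? -R::lgammafn(yi + 1.0)
                       : R::lgammafn(yi + k) - R::lgammafn(k) - R::lgammafn(yi + 1.0);
    cst_cache.emplace(yi, v);
    return v;
  };

  double nll = 0.0;
  NumericVector u_out(J);

  if (sigma2 < 1e-10) {   // no random effect: plain (NB or Poisson) GLM
    for (int i = 0; i < n; ++i) {
      if (poisson) nll -= cst(y[i]) + y[i] * eta[i] - mu0[i];
      else nll -= cst(y[i]) + y[i] * (eta[i] - logk)
                - (y[i] + k) * std::log1p(mu0[i] / k);
    }
    return List::create(_["nll"] = nll, _["u"] = u_out);
  }

  std::vector<double> v(Q);
  for (int j = 0; j < J; ++j) {
    const int lo = subj_start[j], hi = subj_start[j + 1];
    double Cj = 0.0, Sy = 0.0, Smu = 0.0;
    for (int i = lo; i < hi; ++i) {
      Cj += cst(y[i]) + y[i] * (poisson ? eta[i] : eta[i] - logk);
      Sy += y[i];
      Smu += mu0[i];
    }

    // Newton for the conditional mode of u_j (objective is log-concave)
    double u = (j < u_init.size()) ? u_init[j] : 0.0;
    for (int iter = 0; iter < 60; ++iter) {
      double g, h;
      const double eu = std::exp(u);
      if (poisson) {
        g = Sy - Smu * eu - u / sigma2;
        h = -Smu * eu - 1.0 / sigma2;
      } else {
        g = -u / sigma2; h = -1.0 / sigma2;
        for (int i = lo; i < hi; ++i) {
          double mu = mu0[i] * eu;
          double d = k + mu;
          g += (y[i] - mu) * k / d;
          h -= k * mu * (y[i] + k) / (d * d);
        }
      }
      double step = g / h;
      if (!std::isfinite(step)) { u = 0.0; break; }
      if (step > 3.0) step = 3.0;
      if (step < -3.0) step = -3.0;
      u -= step;
      if (std::fabs(step) < 1e-10) break;
    }
    u_out[j] = u;

    double h = -1.0 / sigma2;
    {
      const double eu = std::exp(u);
      if (poisson) {
        h -= Smu * eu;
      } else {
        for (int i = lo; i < hi; ++i) {
          double mu = mu0[i] * eu;
          double d = k + mu;
          h -= k * mu * (y[i] + k) / (d * d);
        }
      }
    }
    const double s = 1.0 / std::sqrt(-h);

    double maxv = R_NegInf;
    for (int q = 0; q < Q; ++q) {
      double t = u + M_SQRT2 * s * z[q];
      double f = Sy * t - t * t / (2.0 * sigma2);
      const double et = std::exp(t);
      if (poisson) {
        f -= Smu * et;
      } else {
        for (int i = lo; i < hi; ++i) {
          f -= (y[i] + k) * std::log1p(mu0[i] * et / k);
        }
      }
      v[q] = std::log(w[q]) + f + z[q] * z[q];
      if (v[q] > maxv) maxv = v[q];
    }
    double sum = 0.0;
    for (int q = 0; q < Q; ++q) sum += std::exp(v[q] - maxv);
    nll -= Cj - 0.5 * std::log(2.0 * M_PI * sigma2) + 0.5 * std::log(2.0)
         + std::log(s) + maxv + std::log(sum);
  }
  return List::create(_["nll"] = nll, _["u"] = u_out);
}
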