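// Numerical kernel for the modified-asymptote mixed logit: per-person
// Gauss-Hermite integration with the track effects held at a given value,
// plus the gradient and Hessian in the track effects needed for the
// Laplace step of the marginal likelihood. Row indices must arrive grouped
// by person. Work arrays are laid out with the quadrature index fastest so
// every inner loop is contiguous.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List asym_glmm_kernel(NumericVector eta0, IntegerVector y,
                      IntegerVector pid, IntegerVector tid,
                      int n_person, int n_track,
                      double sp, NumericVector bt,
                      NumericVector z, NumericVector lw,
                      double g, double u, int want) {
  const int R = eta0.size();
  const int K = z.size();
  const double span = u - g;

  std::vector<double> Pt((size_t)R * K);     // [r*K + k] probabilities
  std::vector<double> A((size_t)n_person * K, 0.0);
  std::vector<double> off(K);
  for (int k = 0; k < K; ++k) off[k] = sp * z[k];

  for (int r = 0; r < R; ++r) {
    const double e0 = eta0[r] + bt[tid[r]];
    double *pr = &Pt[(size_t)r * K];
    double *ai = &A[(size_t)pid[r] * K];
    if (y[r] == 1) {
      for (int k = 0; k < K; ++k) {
        const double p = g + span / (1.0 + std::exp(-(e0 + off[k])));
        pr[k] = p;
        ai[k] += std::log(p);
      }
    } else {
      for (int k = 0; k < K; ++k) {
        const double p = g + span / (1.0 + std::exp(-(e0 + off[k])));
        pr[k] = p;
        ai[k] += std::log1p(-p);
      }
    }
  }

  double ll = 0.0;
  std::vector<double> Wt((size_t)n_person * K);  // posterior node weights
  NumericVector eb(n_person);                    // posterior mean effects
  for (int i = 0; i < n_person; ++i) {
    double *ai = &A[(size_t)i * K];
    double amax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      ai[k] += lw[k];
      if (ai[k] > amax) amax = ai[k];
    }
    double s = 0.0;
    double *wi = &Wt[(size_t)i * K];
    for (int k = 0; k < K; ++k) {
      wi[k] = std::exp(ai[k] - amax);
      s += wi[k];
    }
    double m = 0.0;
    for (int k = 0; k < K; ++k) {
      wi[k] /= s;
      m += wi[k] * z[k];
    }
    eb[i] = sp * m;
    ll += amax + std::log(s);
  }
  if (want == 0)
    return List::create(_["ll"] = ll, _["eb"] = eb);

  // scores s_rk = d log f / d eta and expected scores per row
  std::vector<double> St((size_t)R * K);
  std::vector<double> es(R);
  for (int r = 0; r < R; ++r) {
    const double *pr = &Pt[(size_t)r * K];
    const double *wi = &Wt[(size_t)pid[r] * K];
    double *sr = &St[(size_t)r * K];
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double p = pr[k];
      const double q = (p - g) / span;
      const double dq = span * q * (1.0 - q);
      const double s = (y[r] == 1) ? dq / p : -dq / (1.0 - p);
      sr[k] = s;
      acc += wi[k] * s;
    }
    es[r] = acc;
  }
  NumericVector grad(n_track);
  for (int r = 0; r < R; ++r) grad[tid[r]] += es[r];
  if (want == 1)
    return List::create(_["ll"] = ll, _["eb"] = eb, _["grad"] = grad);

  // Hessian in the track effects (data part only):
  //   direct diagonal term E[s'] plus the within-person score covariance.
  NumericMatrix H(n_track, n_track);
  for (int r = 0; r < R; ++r) {
    const double *pr = &Pt[(size_t)r * K];
    const double *wi = &Wt[(size_t)pid[r] * K];
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double p = pr[k];
      const double q = (p - g) / span;
      const double dq = span * q * (1.0 - q);
      const double d2q = dq * (1.0 - 2.0 * q);
      const double sp2 = (y[r] == 1)
        ? d2q / p - (dq / p) * (dq / p)
        : -d2q / (1.0 - p) - (dq / (1.0 - p)) * (dq / (1.0 - p));
      acc += wi[k] * sp2;
    }
    H(tid[r], tid[r]) += acc;
  }
  // covariance part: rows grouped by person
  int start = 0;
  while (start < R) {
    int end = start;
    while (end < R && pid[end] == pid[start]) ++end;
    const double *wi = &Wt[(size_t)pid[start] * K];
    for (int r1 = start; r1 < end; ++r1) {
      const double *s1 = &St[(size_t)r1 * K];
      for (int r2 = start; r2 < end; ++r2) {
        const double *s2 = &St[(size_t)r2 * K];
        double c = 0.0;
        for (int k = 0; k < K; ++k) c += wi[k] * s1[k] * s2[k];
        H(tid[r1], tid[r2]) += c - es[r1] * es[r2];
      }
    }
    start = end;
  }
  return List::create(_["ll"] = ll, _["eb"] = eb, _["grad"] = grad,
                      _["H"] = H);
}
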