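#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.91893853320467274178;

static inline double gauss_loglik(double x, double m, double s) {
  double z = (x - m) / s;
  return -LOG_SQRT_2PI - std::log(s) - 0.5 * z * z;
}

// Emission log-likelihood matrix (T x K). Missing observations (NA) contribute
// a flat term (log-lik 0 for every state): the decoder bridges them.
static NumericMatrix emission_loglik(const NumericVector& x,
                                     const NumericVector& mean,
                                     const NumericVector& sd) {
  int T = x.size(), K = mean.size();
  NumericMatrix ll(T, K);
  for (int t = 0; t < T; ++t) {
    if (NumericVector::is_na(x[t])) {
      for (int k = 0; k < K; ++k) ll(t, k) = 0.0;
    } else {
      for (int k = 0; k < K; ++k) ll(t, k) = gauss_loglik(x[t], mean[k], sd[k]);
    }
  }
  return ll;
}

// One E-step (scaled forward-backward) on a single trace. Returns the trace
// log-likelihood and the sufficient statistics needed by the M-step:
//   gamma1     P(state at t=1)
//   gamma_sum  sum_t gamma_t(k) over frames with an observation
//   gamma_x    sum_t gamma_t(k) x_t      (observed frames)
//   gamma_x2   sum_t gamma_t(k) x_t^2    (observed frames)
//   xi         sum_t xi_t(i,j)
// [[Rcpp::export]]
List hmm_estep(NumericVector x, NumericVector mean, NumericVector sd,
               NumericMatrix trans, NumericVector init) {
  int T = x.size(), K = mean.size();
  if (T == 0) stop("empty observation sequence");
  NumericMatrix ll = emission_loglik(x, mean, sd);

  // per-frame max-shifted emission likelihoods to avoid underflow
  NumericMatrix b(T, K);
  std::vector<double> bmax(T);
  for (int t = 0; t < T; ++t) {
    double m = ll(t, 0);
    for (int k = 1; k < K; ++k) if (ll(t, k) > m) m = ll(t, k);
    bmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(ll(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  std::vector<double> c(T);

  double s0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s0 += alpha(0, k); }
  if (s0 <= 0) stop("zero forward probability at t=1 (degenerate model)");
  c[0] = s0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s0;

  for (int t = 1; t < T; ++t) {
    double st = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      st += a;
    }
    if (st <= 0) stop("zero forward probability (degenerate model)");
    c[t] = st;
    for (int j = 0; j < K; ++j) alpha(t, j) /= st;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = s / c[t + 1];
    }
  }

  NumericVector gamma1(K), gsum(K), gx(K), gx2(K);
  NumericMatrix xi(K, K);
  std::vector<double> g(K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { g[k] = alpha(t, k) * beta(t, k); norm += g[k]; }
    bool obs = !NumericVector::is_na(x[t]);
    for (int k = 0; k < K; ++k) {
      double gk = g[k] / norm;
      if (t == 0) gamma1[k] = gk;
      if (obs) {
        gsum[k] += gk;
        gx[k] += gk * x[t];
        gx2[k] += gk * x[t] * x[t];
      }
    }
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i) {
      double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + bmax[t];

  return List::create(_["loglik"] = loglik, _["gamma1"] = gamma1,
                      _["gamma_sum"] = gsum, _["gamma_x"] = gx,
                      _["gamma_x2"] = gx2, _["xi"] = xi);
}

// Viterbi decoding with Gaussian emissions. Ties are broken toward the lower
// state index (strict '>' comparisons scanning states in ascending order).
// Returns the 1-based most likely state path and its joint log-probability.
// [[Rcpp::export]]
List hmm_viterbi(NumericVector x, NumericVector mean, NumericVector sd,
                 NumericMatrix trans, NumericVector init) {
  int T = x.size(), K = mean.size();
  if (T == 0) stop("empty observation sequence");
  NumericMatrix ll = emission_loglik(x, mean, sd);

  NumericMatrix lA(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      lA(i, j) = trans(i, j) > 0 ? std::log(trans(i, j)) : R_NegInf;

  std::vector<double> d(K), dn(K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    d[k] = (init[k] > 0 ? std::log(init[k]) : R_NegInf) + ll(0, k);

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = d[0] + lA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = d[i] + lA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      dn[j] = best + ll(t, j);
      psi(t, j) = arg;
    }
    d = dn;
  }

  int last = 0;
  double bestv = d[0];
  for (int k = 1; k < K; ++k)
    if (d[k] > bestv) { bestv = d[k]; last = k; }

  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;

  return List::create(_["path"] = path, _["logprob"] = bestv);
}
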