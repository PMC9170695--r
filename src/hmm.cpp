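#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for a discrete-symbol HMM.
// sym: 0-based symbol index per position (length T)
// pi: initial distribution (K), A: K x K transitions, B: K x S emissions.
// Returns log-likelihood, posterior gamma (T x K) and summed transition
// expectations xi (K x K) for one chain. Work arrays are laid out
// position-major (t*K + k) so the t-recursions stay cache-local.
// [[Rcpp::export]]
List hmm_forward_backward(IntegerVector sym, NumericVector pi,
                          NumericMatrix A, NumericMatrix B) {
  const int T = sym.size();
  const int K = pi.size();
  const int S = B.ncol();
  std::vector<double> a(K * K), b(K * S);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) a[j * K + k] = A(j, k);   // row-major A
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) b[s * K + k] = B(k, s);   // symbol-major B

  std::vector<double> alpha(static_cast<size_t>(T) * K);
  std::vector<double> beta(static_cast<size_t>(T) * K);
  std::vector<double> c(T);
  const int* sy = INTEGER(sym);

  // forward
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = pi[k] * b[sy[0] * K + k];
    s0 += alpha[k];
  }
  if (s0 <= 0.0) stop("zero-probability observation at position 1");
  c[0] = s0;
  for (int k = 0; k < K; ++k) alpha[k] /= s0;
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha[static_cast<size_t>(t - 1) * K];
    double* an = &alpha[static_cast<size_t>(t) * K];
    const double* bt = &b[sy[t] * K];
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += ap[j] * a[j * K + k];
      v *= bt[k];
      an[k] = v;
      s += v;
    }
    if (s <= 0.0) stop("zero-probability observation at position ", t + 1);
    c[t] = s;
    for (int k = 0; k < K; ++k) an[k] /= s;
  }

  // backward (scaled by the same c)
  for (int k = 0; k < K; ++k) beta[static_cast<size_t>(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double* bn = &beta[static_cast<size_t>(t + 1) * K];
    double* bp = &beta[static_cast<size_t>(t) * K];
    const double* bt = &b[sy[t + 1] * K];
    const double ci = 1.0 / c[t + 1];
    for (int k = 0; k < K; ++k) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += a[k * K + j] * bt[j] * bn[j];
      bp[k] = v * ci;
    }
  }

  // posteriors and summed transition expectations
  NumericMatrix gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> xacc(K * K, 0.0);
  for (int t = 0; t < T; ++t) {
    const double* ap = &alpha[static_cast<size_t>(t) * K];
    const double* bp = &beta[static_cast<size_t>(t) * K];
    double g = 0.0;
    for (int k = 0; k < K; ++k) g += ap[k] * bp[k];
    for (int k = 0; k < K; ++k) gamma(t, k) = ap[k] * bp[k] / g;
  }
  for (int t = 0; t < T - 1; ++t) {
    const double* ap = &alpha[static_cast<size_t>(t) * K];
    const double* bn = &beta[static_cast<size_t>(t + 1) * K];
    const double* bt = &b[sy[t + 1] * K];
    const double ci = 1.0 / c[t + 1];
    for (int k = 0; k < K; ++k) {
      const double ak = ap[k] * ci;
      for (int j = 0; j < K; ++j)
        xacc[k * K + j] += ak * a[k * K + j] * bt[j] * bn[j];
    }
  }
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j) xi(k, j) = xacc[k * K + j];

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Viterbi decoding in log space. Inputs are logs; returns the 0-based
// maximum-probability state path and its log-probability.
// [[Rcpp::export]]
List hmm_viterbi(IntegerVector sym, NumericVector logpi,
                 NumericMatrix logA, NumericMatrix logB) {
  const int T = sym.size();
  const int K = logpi.size();
  const int S = logB.ncol();
  std::vector<double> a(K * K), b(K * S);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) a[j * K + k] = logA(j, k);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) b[s * K + k] = logB(k, s);

  std::vector<double> delta(static_cast<size_t>(T) * K);
  std::vector<int> psi(static_cast<size_t>(T) * K);
  const int* sy = INTEGER(sym);
  for (int k = 0; k < K; ++k) delta[k] = logpi[k] + b[sy[0] * K + k];
  for (int t = 1; t < T; ++t) {
    const double* dp = &delta[static_cast<size_t>(t - 1) * K];
    double* dn = &delta[static_cast<size_t>(t) * K];
    int* pn = &psi[static_cast<size_t>(t) * K];
    const double* bt = &b[sy[t] * K];
    for (int k = 0; k < K; ++k) {
      double best = dp[0] + a[k];
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = dp[j] + a[j * K + k];
        if (v > best) { best = v; arg = j; }
      }
      dn[k] = best + bt[k];
      pn[k] = arg;
    }
  }
  IntegerVector path(T);
  const double* dl = &delta[static_cast<size_t>(T - 1) * K];
  double best = dl[0];
  path[T - 1] = 0;
  for (int k = 1; k < K; ++k)
    if (dl[k] > best) { best = dl[k]; path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[static_cast<size_t>(t + 1) * K + path[t + 1]];
  return List::create(_["path"] = path, _["logprob"] = best);
}
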