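#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one contiguous segment.
// logB: T x NS matrix of emission log-probabilities, A: NS x NS row-stochastic
// transition matrix, pi0: initial state distribution.  Per-bin rescaling keeps
// the recursion in the normalized domain, so T up to 1e6 cannot underflow.
// Returns gamma (T x NS posterior), xi (NS x NS expected transition counts
// summed over t) and the marginal log-likelihood of the segment.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix A, NumericVector pi0,
             bool want_xi) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix btil(T, S);       // exp(logB - rowmax), per-row shift
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logB(t, s));
    shift[t] = m;
    for (int s = 0; s < S; ++s) btil(t, s) = std::exp(logB(t, s) - m);
  }

  NumericMatrix alpha(T, S);
  NumericVector c(T);             // scaling constants
  double loglik = 0.0;
  for (int s = 0; s < S; ++s) alpha(0, s) = pi0[s] * btil(0, s);
  double c0 = 0.0;
  for (int s = 0; s < S; ++s) c0 += alpha(0, s);
  if (c0 <= 0.0) stop("zero forward mass at t=1 (impossible observation)");
  c[0] = c0;
  for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
  loglik += std::log(c0) + shift[0];

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int j = 0; j < S; ++j) {
      double acc = 0.0;
      for (int i = 0; i < S; ++i) acc += alpha(t - 1, i) * A(i, j);
      double v = acc * btil(t, j);
      alpha(t, j) = v;
      ct += v;
    }
    if (ct <= 0.0) stop("zero forward mass (impossible observation)");
    c[t] = ct;
    for (int j = 0; j < S; ++j) alpha(t, j) /= ct;
    loglik += std::log(ct) + shift[t];
  }

  NumericMatrix gamma(T, S);
  NumericMatrix xi(S, S);
  std::vector<double> beta(S, 1.0), betanew(S);
  for (int s = 0; s < S; ++s) gamma(T - 1, s) = alpha(T - 1, s);
  for (int t = T - 2; t >= 0; --t) {
    // w_j = btil(t+1, j) * beta_j / c_{t+1}
    std::vector<double> w(S);
    for (int j = 0; j < S; ++j) w[j] = btil(t + 1, j) * beta[j] / c[t + 1];
    for (int i = 0; i < S; ++i) {
      double acc = 0.0;
      for (int j = 0; j < S; ++j) {
        double term = A(i, j) * w[j];
        if (want_xi) xi(i, j) += alpha(t, i) * term;
        acc += term;
      }
      betanew[i] = acc;
      gamma(t, i) = alpha(t, i) * acc;
    }
    for (int i = 0; i < S; ++i) beta[i] = betanew[i];
    // guard against drift: renormalize the gamma row
    double g = 0.0;
    for (int i = 0; i < S; ++i) g += gamma(t, i);
    if (g > 0.0) for (int i = 0; i < S; ++i) gamma(t, i) /= g;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// Markov-chain simulation: init is a 0-based start state, u a vector of
// uniforms (drawn in R so set.seed() governs reproducibility).  Returns
// 1-based states of length length(u) + 1.
// [[Rcpp::export(name = ".sim_chain_core")]]
IntegerVector sim_chain_core(NumericMatrix A, int init, NumericVector u) {
  const int S = A.nrow();
  const int n = u.size() + 1;
  IntegerVector st(n);
  int cur = init;
  st[0] = cur + 1;
  for (int t = 1; t < n; ++t) {
    double acc = 0.0;
    int nxt = S - 1;
    for (int j = 0; j < S; ++j) {
      acc += A(cur, j);
      if (u[t - 1] < acc) { nxt = j; break; }
    }
    cur = nxt;
    st[t] = cur + 1;
  }
  return st;
}
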