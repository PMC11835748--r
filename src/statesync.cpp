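#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass over one segment. logB is T x K emission log-densities.
// Per-volume scaling keeps the recursion in linear domain without underflow;
// the returned log-likelihood is exact.
static double forward_segment(const NumericMatrix& logB, int from, int to,
                              const NumericMatrix& trans,
                              const NumericVector& init,
                              NumericMatrix* alpha_out) {
  const int K = logB.ncol();
  double ll = 0.0;
  std::vector<double> alpha(K), tmp(K);

  for (int t = from; t <= to; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    for (int k = 0; k < K; ++k) tmp[k] = std::exp(logB(t, k) - m);
    double c = 0.0;
    if (t == from) {
      for (int k = 0; k < K; ++k) { alpha[k] = init[k] * tmp[k]; c += alpha[k]; }
    } else {
      std::vector<double> prev(alpha);
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += prev[j] * trans(j, k);
        alpha[k] = s * tmp[k];
        c += alpha[k];
      }
    }
    if (c <= 0.0) return R_NegInf;
    for (int k = 0; k < K; ++k) alpha[k] /= c;
    if (alpha_out) for (int k = 0; k < K; ++k) (*alpha_out)(t, k) = alpha[k];
    ll += std::log(c) + m;
  }
  return ll;
}

// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix logB, NumericMatrix trans,
                          NumericVector init, IntegerVector seg_starts,
                          IntegerVector seg_ends) {
  double ll = 0.0;
  for (int s = 0; s < seg_starts.size(); ++s)
    ll += forward_segment(logB, seg_starts[s] - 1, seg_ends[s] - 1, trans, init, nullptr);
  return ll;
}

// Full E-step: posterior state probabilities (gamma), expected transition
// counts (xi, summed over time and segments), expected initial-state counts,
// and total log-likelihood. Forward-backward restarts at each segment.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix logB, NumericMatrix trans,
                          NumericVector init, IntegerVector seg_starts,
                          IntegerVector seg_ends) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix gamma(T, K), alpha(T, K), xi(K, K);
  NumericVector init_counts(K);
  NumericVector cvec(T), mvec(T);
  double ll = 0.0;

  for (int s = 0; s < seg_starts.size(); ++s) {
    int from = seg_starts[s] - 1, to = seg_ends[s] - 1;
    // forward, storing scaled alpha plus scaling constants
    std::vector<double> a(K), tmp(K);
    for (int t = from; t <= to; ++t) {
      double m = logB(t, 0);
      for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
      mvec[t] = m;
      for (int k = 0; k < K; ++k) tmp[k] = std::exp(logB(t, k) - m);
      double c = 0.0;
      if (t == from) {
        for (int k = 0; k < K; ++k) { a[k] = init[k] * tmp[k]; c += a[k]; }
      } else {
        std::vector<double> prev(a);
        for (int k = 0; k < K; ++k) {
          double acc = 0.0;
          for (int j = 0; j < K; ++j) acc += prev[j] * trans(j, k);
          a[k] = acc * tmp[k];
          c += a[k];
        }
      }
      if (c <= 0.0) stop("forward pass underflow: zero total probability at a volume");
      for (int k = 0; k < K; ++k) { a[k] /= c; alpha(t, k) = a[k]; }
      cvec[t] = c;
      ll += std::log(c) + m;
    }
    // backward with the same scaling; gamma and xi are exact posteriors
    std::vector<double> b(K, 1.0), bnext(K), btmp(K);
    for (int k = 0; k < K; ++k) gamma(to, k) = alpha(to, k);
    for (int t = to - 1; t >= from; --t) {
      for (int k = 0; k < K; ++k)
        btmp[k] = std::exp(logB(t + 1, k) - mvec[t + 1]) * b[k];
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += trans(j, k) * btmp[k];
        bnext[j] = acc / cvec[t + 1];
      }
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi(j, k) += alpha(t, j) * trans(j, k) * btmp[k] / cvec[t + 1];
      b = bnext;
      double norm = 0.0;
      for (int k = 0; k < K; ++k) norm += alpha(t, k) * b[k];
      for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * b[k] / norm;
    }
    for (int k = 0; k < K; ++k) init_counts[k] += gamma(from, k);
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi,
                      _["init_counts"] = init_counts);
}

// Viterbi decoding in the log domain; ties broken toward the lowest state
// index (strict inequality keeps the earliest maximiser).
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix log_trans,
                          NumericVector log_init) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  IntegerVector path(T);

  for (int k = 0; k < K; ++k) delta(0, k) = log_init[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + log_trans(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + log_trans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return path;
}

// Simulate n independent Markov chains of length T from a row-stochastic
// transition matrix, using R's RNG stream (so set.seed() governs output).
// [[Rcpp::export]]
IntegerMatrix sim_markov_cpp(NumericMatrix trans, NumericVector init,
                             int T, int n) {
  const int K = trans.nrow();
  IntegerMatrix out(T, n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand(), acc = 0.0;
    int s = K - 1;
    for (int k = 0; k < K; ++k) { acc += init[k]; if (u < acc) { s = k; break; } }
    out(0, i) = s + 1;
    for (int t = 1; t < T; ++t) {
      u = unif_rand(); acc = 0.0;
      int nxt = K - 1;
      for (int k = 0; k < K; ++k) { acc += trans(s, k); if (u < acc) { nxt = k; break; } }
      s = nxt;
      out(t, i) = s + 1;
    }
  }
  return out;
}
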