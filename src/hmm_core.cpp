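#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a (possibly inhomogeneous-emission) HMM.
// logB: T x K log emission densities (or expected log densities under VB),
// logA: K x K log transition matrix, logpi: length-K log initial distribution.
// Returns gamma (T x K smoothing posteriors), xi (K x K summed pairwise
// transition posteriors over t = 1..T-1) and the log normalizer (log-likelihood
// when point parameters are supplied).
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));

  NumericMatrix b(T, K);      // scaled emission likelihoods
  NumericVector bmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    bmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - m);
  }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(logpi[k]) * b(0, k);
    s += alpha(0, k);
  }
  if (!(s > 0.0)) stop("forward pass underflow at t=1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (!(s > 0.0)) stop("forward pass underflow at t=%d", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = a / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t) {
    double z = 0.0;
    // xi_t(i,j) proportional to alpha_t(i) A_ij b_{t+1}(j) beta_{t+1}(j)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        z += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / z;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + bmax[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// Returns a 1-based integer path of length T.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      int arg = 0;
      double best = delta(t - 1, 0) + logA(0, j);
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }   // strict > keeps lowest index on ties
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Sample a (possibly event-modulated) Markov chain. u holds T pre-drawn
// uniforms so determinism is owned by R's RNG. boost is a T x K matrix of
// multiplicative factors applied to the transition row (then renormalized);
// pass a 0 x 0 matrix for the homogeneous chain.
// [[Rcpp::export]]
IntegerVector markov_path_cpp(NumericMatrix A, NumericVector pi0,
                              NumericVector u, NumericMatrix boost) {
  const int T = u.size(), K = A.ncol();
  const bool mod = boost.nrow() == T && boost.ncol() == K;
  IntegerVector path(T);
  std::vector<double> p(K);

  auto draw = [&](const std::vector<double>& prob, double uu) {
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      acc += prob[k];
      if (uu <= acc) return k;
    }
    return K - 1;
  };

  double z = 0.0;
  for (int k = 0; k < K; ++k) {
    p[k] = pi0[k] * (mod ? boost(0, k) : 1.0);
    z += p[k];
  }
  for (int k = 0; k < K; ++k) p[k] /= z;
  int cur = draw(p, u[0]);
  path[0] = cur + 1;

  for (int t = 1; t < T; ++t) {
    z = 0.0;
    for (int k = 0; k < K; ++k) {
      p[k] = A(cur, k) * (mod ? boost(t, k) : 1.0);
      z += p[k];
    }
    for (int k = 0; k < K; ++k) p[k] /= z;
    cur = draw(p, u[t]);
    path[t] = cur + 1;
  }
  return path;
}
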