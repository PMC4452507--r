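#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic gradient descent core for the sigmoid-output factorization.
//
// Per sample (i, j) with label y: F = sigmoid(a_i . b_j), e = y - F, and
//   a_i <- a_i + eta * (e * F * (1 - F) * b_j - lambda * a_i)
//   b_j <- b_j + eta * (e * F * (1 - F) * a_i - lambda * b_j)
// using the pre-update a_i in b_j's rule (simultaneous update).  The dot
// product is clipped to +/- 30 before the exponential.
//
// `order` holds one 0-based visiting permutation per epoch (n x max_epochs);
// shuffles are generated on the R side so determinism follows R's RNG.
// Training stops when the relative change of the full objective between
// consecutive epochs drops below `tol`, or after max_epochs.  A non-finite
// objective aborts with the 1-based epoch index in `diverged`.

static inline double clip30(double x) {
  if (x > 30.0) return 30.0;
  if (x < -30.0) return -30.0;
  return x;
}

// [[Rcpp::export]]
List mf_sgd_core(NumericMatrix A0, NumericMatrix B0,
                 IntegerVector di, IntegerVector si, NumericVector y,
                 IntegerMatrix order, double eta, double lambda,
                 double tol, int max_epochs) {
  const int n = di.size();
  const int k = A0.ncol();
  NumericMatrix A = clone(A0);
  NumericMatrix B = clone(B0);
  std::vector<double> trace;
  trace.reserve(max_epochs);

  // objective of the incoming model: the first epoch's convergence test
  // compares against it
  double prev = 0.0;
  for (int s = 0; s < n; ++s) {
    const int i = di[s];
    const int j = si[s];
    double dot = 0.0, na = 0.0, nb = 0.0;
    for (int c = 0; c < k; ++c) {
      dot += A(i, c) * B(j, c);
      na += A(i, c) * A(i, c);
      nb += B(j, c) * B(j, c);
    }
    const double f = 1.0 / (1.0 + std::exp(-clip30(dot)));
    const double d = y[s] - f;
    prev += d * d + lambda * (na + nb);
  }
  prev *= 0.5;

  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int t = 0; t < n; ++t) {
      const int s = order(t, ep);
      const int i = di[s];
      const int j = si[s];
      double dot = 0.0;
      for (int c = 0; c < k; ++c) dot += A(i, c) * B(j, c);
      const double f = 1.0 / (1.0 + std::exp(-clip30(dot)));
      const double g = (y[s] - f) * f * (1.0 - f);
      for (int c = 0; c < k; ++c) {
        const double ai = A(i, c);
        const double bj = B(j, c);
        A(i, c) = ai + eta * (g * bj - lambda * ai);
        B(j, c) = bj + eta * (g * ai - lambda * bj);
      }
    }
    // full objective: (1/2) sum_s [(y - F)^2 + lambda (||a_i||^2 + ||b_j||^2)]
    double L = 0.0;
    for (int s = 0; s < n; ++s) {
      const int i = di[s];
      const int j = si[s];
      double dot = 0.0, na = 0.0, nb = 0.0;
      for (int c = 0; c < k; ++c) {
        dot += A(i, c) * B(j, c);
        na += A(i, c) * A(i, c);
        nb += B(j, c) * B(j, c);
      }
      const double f = 1.0 / (1.0 + std::exp(-clip30(dot)));
      const double d = y[s] - f;
      L += d * d + lambda * (na + nb);
    }
    L *= 0.5;
    if (!std::isfinite(L)) {
      return List::create(_["diverged"] = ep + 1);
    }
    trace.push_back(L);
    const double denom = std::max(prev, 1e-12);
    if (std::fabs(prev - L) / denom < tol) break;
    prev = L;
  }
  return List::create(
      _["A"] = A, _["B"] = B,
      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
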