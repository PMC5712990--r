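#include <Rcpp.h>
using namespace Rcpp;

// Time-stepping recursion of an MAR(p) process:
//   x(t) = sum_{tau=1..p} t(A(tau)) %*% x(t - tau) + e(t)
// coef_t: M x (M*p) matrix, block tau holding t(A(tau));
// innov:  total x M matrix of innovations (burn-in rows included);
// the state before t = 0 is zero.
// [[Rcpp::export]]
NumericMatrix mar_recurse_cpp(NumericMatrix coef_t, NumericMatrix innov,
                              int p) {
  const int total = innov.nrow();
  const int M = innov.ncol();
  if (coef_t.nrow() != M || coef_t.ncol() != M * p)
    stop("coefficient matrix has inconsistent dimensions");
  NumericMatrix X(total, M);
  for (int t = 0; t < total; ++t) {
    const int K = std::min(p, t);
    for (int m = 0; m < M; ++m) {
      double acc = innov(t, m);
      for (int tau = 1; tau <= K; ++tau) {
        const int off = (tau - 1) * M;
        for (int k = 0; k < M; ++k)
          acc += coef_t(m, off + k) * X(t - tau, k);
      }
      X(t, m) = acc;
    }
  }
  return X;
}
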