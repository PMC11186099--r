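// Non-negative least squares for many right-hand sides sharing one design.
// Lawson-Hanson active-set on the normal equations; the Gram matrix W'W is
// computed once and reused across all cells, which is what makes refitting
// program activities over thousands of cells cheap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min ||W x - v||^2 s.t. x >= 0 given WtW (k x k) and Wtv (k).
static vec nnls_one(const mat& WtW, const vec& Wtv, const double tol) {
  const uword k = WtW.n_rows;
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);  // 0 = active (zero), 1 = passive (free)
  vec w = Wtv;                   // gradient of -0.5 objective at x = 0

  for (uword outer = 0; outer < 30 * k + 30; ++outer) {
    // most-violating zero coordinate
    double wmax = tol; sword jmax = -1;
    for (uword j = 0; j < k; ++j)
      if (!passive(j) && w(j) > wmax) { wmax = w(j); jmax = j; }
    if (jmax < 0) break;
    passive(jmax) = 1;

    // inner loop: solve on passive set, step back if infeasible
    for (;;) {
      uvec P = find(passive == 1);
      vec z(k, fill::zeros);
      vec zp = solve(WtW.submat(P, P), Wtv.elem(P),
                     solve_opts::likely_sympd);
      z.elem(P) = zp;
      if (zp.min() > 0) { x = z; break; }
      double alpha = datum::inf;
      for (uword t = 0; t < P.n_elem; ++t) {
        uword j = P(t);
        if (z(j) <= 0) {
          double a = x(j) / (x(j) - z(j));
          if (a < alpha) alpha = a;
        }
      }
      x += alpha * (z - x);
      for (uword t = 0; t < P.n_elem; ++t) {
        uword j = P(t);
        if (x(j) <= tol * std::max(1.0, std::abs(z(j)))) {
          x(j) = 0; passive(j) = 0;
        }
      }
    }
    w = Wtv - WtW * x;
  }
  return x;
}

// [[Rcpp::export(name = ".nnls_cols_cpp")]]
arma::mat nnls_cols_cpp(const arma::mat& W, const arma::mat& X) {
  const mat WtW = W.t() * W;
  const mat WtX = W.t() * X;
  const double tol = 1e-10 * std::max(1.0, WtW.max());
  mat H(W.n_cols, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c)
    H.col(c) = nnls_one(WtW, WtX.col(c), tol);
  return H;
}
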