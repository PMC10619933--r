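// Lawson-Hanson active-set non-negative least squares.
//
// Solves min ||A x - b||_2 subject to x >= 0.  This is the inner kernel of
// the voxelwise multicomponent T2 analysis (dictionary fitting, flip-angle
// search, and regularized refits all reduce to NNLS on stacked systems), so
// it is compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nnls_lh(const arma::mat& A, const arma::vec& b,
                   double tol = -1.0, int max_iter = -1) {
  const uword n = A.n_cols;
  if (max_iter < 0) max_iter = 3 * static_cast<int>(n);
  if (tol < 0) {
    tol = 10.0 * datum::eps * norm(A, 1) * static_cast<double>(A.n_rows);
  }

  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * b;           // gradient of 0.5||Ax-b||^2 at x = 0 (negated)
  int outer = 0;

  while (outer < max_iter) {
    // pick the most violating zero variable
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
    }
    if (t < 0) break;          // KKT satisfied
    passive[t] = true;
    ++outer;

    for (;;) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast);
      if (!ok) {
        z = pinv(A.cols(P)) * b;
      }
      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step back to the feasibility boundary
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double xa = x(P(k));
          double a = xa / (xa - z(k));
          if (a < alpha) alpha = a;
        }
      }
      for (uword k = 0; k < np; ++k) {
        double xnew = x(P(k)) + alpha * (z(k) - x(P(k)));
        x(P(k)) = xnew;
      }
      for (uword k = 0; k < np; ++k) {
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
      }
    }
    w = A.t() * (b - A * x);
  }

  vec r = b - A * x;
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("resnorm") = dot(r, r),
                            Rcpp::Named("iterations") = outer,
                            Rcpp::Named("converged") = outer < max_iter);
}
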