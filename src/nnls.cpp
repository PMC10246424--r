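#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   min ||A x - b||_2  s.t.  x >= 0
// Returns the coefficient vector. Deterministic; no randomness involved.
// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::NumericVector nnls_cpp(const arma::mat& A, const arma::vec& b,
                             double tol = -1.0, int max_iter = -1) {
  const uword n = A.n_cols;
  if (max_iter < 0) max_iter = 3 * (int)n + 30;
  if (tol < 0) tol = 10.0 * datum::eps * norm(A, "fro") * (double)A.n_rows;

  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);

  int outer = 0;
  while (outer++ < max_iter) {
    // most-violating free variable
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    passive[t] = true;

    // inner loop: solve on passive set, back off along the segment if any
    // passive coefficient would go negative
    for (int inner = 0; inner < max_iter; ++inner) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b);
      if (!ok) {  // rank-deficient subproblem: ridge-stabilised fallback
        mat AtA = A.cols(P).t() * A.cols(P);
        AtA.diag() += 1e-12 * trace(AtA) / (double)np;
        z = solve(AtA, A.cols(P).t() * b);
      }
      if (np == 0 || z.min() > 0) {
        x.zeros();
        for (uword k = 0; k < np; ++k) x(P(k)) = z(k);
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double a = x(P(k)) / (x(P(k)) - z(k));
          if (a < alpha) alpha = a;
        }
      for (uword k = 0; k < np; ++k)
        x(P(k)) += alpha * (z(k) - x(P(k)));
      for (uword k = 0; k < np; ++k)
        if (x(P(k)) <= tol) { passive[P(k)] = false; x(P(k)) = 0.0; }
    }
    w = A.t() * (b - A * x);
  }
  return Rcpp::wrap(x);
}
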