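#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double u, double l) {
  if (u > l) return u - l;
  if (u < -l) return u + l;
  return 0.0;
}

// Cyclic coordinate descent for the lasso
//   min_b 1/(2n) ||y - X b||^2 + lambda ||b||_1
// over a decreasing lambda sequence with warm starts. Columns should be
// centred (y too); unit column scale is not required. Coordinates are
// screened with the sequential strong rule |x_j'r|/n >= 2*lam_l - lam_{l-1};
// after convergence on the screened set a full Karush-Kuhn-Tucker pass over
// all coordinates admits any violators and iteration continues until none
// remain. Convergence: largest absolute coefficient change in a sweep
// below tol.
// [[Rcpp::export]]
arma::mat lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambdas, const double tol = 1e-7,
                         const int maxit = 100000) {
  const uword n = X.n_rows, m = X.n_cols, L = lambdas.n_elem;
  mat B(m, L, fill::zeros);
  vec b(m, fill::zeros);
  vec r = y;
  vec xx(m);                      // x_j' x_j / n
  for (uword j = 0; j < m; ++j) xx(j) = dot(X.col(j), X.col(j)) / n;

  std::vector<uword> ever;        // screened coordinate set
  std::vector<char> in_set(m, 0);

  for (uword l = 0; l < L; ++l) {
    const double lam = lambdas(l);
    const double lam_prev = (l == 0) ? lambdas(0) : lambdas(l - 1);
    // rebuild the screened set: current actives + sequential strong rule
    {
      ever.clear();
      std::fill(in_set.begin(), in_set.end(), 0);
      vec g = X.t() * r / n;
      double thr = 2.0 * lam - lam_prev;
      for (uword j = 0; j < m; ++j) {
        if (b(j) != 0.0 || std::fabs(g(j)) >= thr) {
          in_set[j] = 1;
          ever.push_back(j);
        }
      }
    }
    int it = 0;
    while (it < maxit) {
      // iterate on the screened set until converged
      while (it < maxit) {
        double maxdel = 0.0;
        for (uword idx = 0; idx < ever.size(); ++idx) {
          uword j = ever[idx];
          if (xx(j) <= 0.0) continue;
          double u = b(j) * xx(j) + dot(X.col(j), r) / n;
          double bn = soft(u, lam) / xx(j);
          double d = bn - b(j);
          if (d != 0.0) {
            r -= X.col(j) * d;
            b(j) = bn;
            double ad = std::fabs(d);
            if (ad > maxdel) maxdel = ad;
          }
        }
        ++it;
        if (maxdel < tol) break;
      }
      // full KKT check; admit violators and continue if any
      vec g = X.t() * r / n;
      bool viol = false;
      for (uword j = 0; j < m; ++j) {
        if (!in_set[j] && std::fabs(g(j)) > lam) {
          in_set[j] = 1;
          ever.push_back(j);
          viol = true;
        }
      }
      if (!viol) break;
    }
    B.col(l) = b;
  }
  return B;
}
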