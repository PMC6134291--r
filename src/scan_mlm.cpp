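#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// The rotated REML profile criterion only needs weighted inner products
// among the columns of [Xf, y] with weights w_i = 1/(lam_i + delta). All
// pairwise element products are precomputed once per marker (the pairs not
// involving the marker are shared across markers), so each delta
// evaluation is one gemv plus a (p+1)x(p+1) Cholesky.
struct ScanWork {
  const vec& lam;
  mat P;        // n x npair pairwise products of [Xf, y]
  uword p;      // ncol(Xf)
  uword n;
  // scratch filled by eval():
  double yPy = 0.0, logdetA = 0.0;
  vec beta;
  mat Ainv;

  ScanWork(const vec& lam_, uword n_, uword p_)
      : lam(lam_), P(n_, (p_ + 2) * (p_ + 1) / 2), p(p_), n(n_) {}

  // criterion to maximize; returns -inf when the weighted normal matrix is
  // singular (e.g. a constant marker)
  double eval(double delta, bool want_coef) {
    vec w = 1.0 / (lam + delta);
    vec s = P.t() * w;                      // all weighted inner products
    mat A(p, p);
    vec b(p);
    uword k = 0;
    for (uword i = 0; i < p + 1; ++i) {
      for (uword j = i; j < p + 1; ++j, ++k) {
        if (j < p) A(i, j) = A(j, i) = s(k);
        else if (i < p) b(i) = s(k);
      }
    }
    double yWy = s(s.n_elem - 1);
    mat R;
    if (!chol(R, A)) return -datum::inf;
    vec z = solve(trimatl(R.t()), b);
    yPy = yWy - dot(z, z);
    if (yPy <= 0 || !std::isfinite(yPy)) return -datum::inf;
    logdetA = 2.0 * sum(log(R.diag()));
    if (want_coef) {
      beta = solve(trimatu(R), z);
      mat Rinv = inv(trimatu(R));
      Ainv = Rinv * Rinv.t();
    }
    double np = (double)(n - p);
    return -0.5 * (np * std::log(yPy) + sum(log(lam + delta)) + logdetA);
  }
};

// Exact single-locus mixed-model scan on rotated data: for every marker
// the variance ratio delta = sigma_e^2/sigma_g^2 is re-optimized (coarse
// log10 grid then golden-section refinement) and the marker's GLS effect,
// standard error and t statistic are taken at the optimum.
// [[Rcpp::export]]
Rcpp::List scan_mlm_cpp(const arma::mat& UtX, const arma::vec& Uty,
                        const arma::mat& UtG, const arma::vec& lam,
                        const int ngrid = 21, const double l10lo = -5.0,
                        const double l10hi = 5.0) {
  const uword n = Uty.n_elem, p0 = UtX.n_cols, m = UtG.n_cols;
  const uword p = p0 + 1;
  vec effect(m, fill::zeros), se(m, fill::value(datum::nan));
  vec tstat(m, fill::zeros), delta_out(m, fill::value(datum::nan));
  vec sg2_out(m, fill::value(datum::nan));
  ivec ok(m, fill::zeros);

  ScanWork wk(lam, n, p);
  // pair layout over v = [X (p0 cols), x, y]: column index k runs over
  // (i, j) with i <= j in the order used by eval(). Pairs not involving
  // the marker are filled once.
  const uword nv = p + 1;
  std::vector<std::pair<uword, uword>> pairs;
  for (uword i = 0; i < nv; ++i)
    for (uword j = i; j < nv; ++j) pairs.push_back({i, j});
  auto col_of = [&](uword idx) -> vec {
    if (idx < p0) return UtX.col(idx);
    if (idx == p0) return vec();           // marker, filled per j
    return Uty;
  };
  for (uword k = 0; k < pairs.size(); ++k) {
    uword i = pairs[k].first, j = pairs[k].second;
    if (i == p0 || j == p0) continue;
    wk.P.col(k) = col_of(i) % col_of(j);
  }

  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  vec grid(ngrid);
  for (int g = 0; g < ngrid; ++g)
    grid(g) = l10lo + (l10hi - l10lo) * g / (ngrid - 1.0);

  for (uword jm = 0; jm < m; ++jm) {
    vec x = UtG.col(jm);
    for (uword k = 0; k < pairs.size(); ++k) {
      uword i = pairs[k].first, j = pairs[k].second;
      if (i != p0 && j != p0) continue;
      const vec& other = (i == p0) ? (j == p0 ? x : col_of(j)) : col_of(i);
      wk.P.col(k) = x % other;
    }
    int best = -1;
    double fbest = -datum::inf;
    for (int g = 0; g < ngrid; ++g) {
      double f = wk.eval(std::pow(10.0, grid(g)), false);
      if (f > fbest) { fbest = f; best = g; }
    }
    if (best < 0) continue;  // singular at every delta (constant marker)
    double a = grid(std::max(best - 1, 0));
    double b = grid(std::min(best + 1, ngrid - 1));
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = wk.eval(std::pow(10.0, x1), false);
    double f2 = wk.eval(std::pow(10.0, x2), false);
    for (int it = 0; it < 48; ++it) {
      if (f1 < f2) {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = wk.eval(std::pow(10.0, x2), false);
      } else {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = wk.eval(std::pow(10.0, x1), false);
      }
    }
    double dopt = std::pow(10.0, (a + b) / 2.0);
    double f = wk.eval(dopt, true);
    if (!std::isfinite(f)) continue;
    double sg2 = wk.yPy / (double)(n - p);
    double v = sg2 * wk.Ainv(p - 1, p - 1);
    if (v <= 0 || !std::isfinite(v)) continue;
    effect(jm) = wk.beta(p - 1);
    se(jm) = std::sqrt(v);
    tstat(jm) = effect(jm) / se(jm);
    delta_out(jm) = dopt;
    sg2_out(jm) = sg2;
    ok(jm) = 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("effect") = effect, Rcpp::Named("se") = se,
      Rcpp::Named("t") = tstat, Rcpp::Named("delta") = delta_out,
      Rcpp::Named("sigma_g2") = sg2_out, Rcpp::Named("ok") = ok,
      Rcpp::Named("df") = (double)(n - p));
}
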