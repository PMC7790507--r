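#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Stabilized Sinkhorn scaling iterations (log-absorption): scaling vectors
// are absorbed into the dual potentials and the kernel rebuilt whenever they
// leave a safe numeric range, so very small lam is handled without underflow.
// Mirrors the semantics of the R reference loop in R/ot.R.
// [[Rcpp::export]]
Rcpp::List sinkhorn_core_cpp(const arma::mat& cost, const arma::vec& a,
                             const arma::vec& b, const double lam,
                             const double tol, const int max_iter,
                             arma::vec f, arma::vec g) {
  const arma::uword n = a.n_elem, m = b.n_elem;
  const double xmin = std::numeric_limits<double>::min();
  const double tau = 1e100;
  arma::mat K(n, m);
  auto rebuild = [&]() {
    for (arma::uword j = 0; j < m; ++j)
      for (arma::uword i = 0; i < n; ++i)
        K(i, j) = std::exp((f(i) + g(j) - cost(i, j)) / lam);
  };
  rebuild();
  arma::vec u(n, arma::fill::ones), v(m, arma::fill::ones);
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    ++it;
    arma::vec Kv = K * v;
    for (arma::uword i = 0; i < n; ++i)
      u(i) = a(i) / std::max(Kv(i), xmin);
    arma::vec Ktu = K.t() * u;
    double err = 0.0;
    bool finite = true;
    for (arma::uword j = 0; j < m; ++j) {
      double e = std::abs(v(j) * Ktu(j) - b(j));
      if (!std::isfinite(e)) { finite = false; break; }
      if (e > err) err = e;
    }
    if (finite && err < tol) { converged = true; break; }
    for (arma::uword j = 0; j < m; ++j)
      v(j) = b(j) / std::max(Ktu(j), xmin);
    if (!finite || u.max() > tau || v.max() > tau ||
        !u.is_finite() || !v.is_finite()) {
      for (arma::uword i = 0; i < n; ++i)
        f(i) += lam * std::log(std::max(u(i), xmin));
      for (arma::uword j = 0; j < m; ++j)
        g(j) += lam * std::log(std::max(v(j), xmin));
      rebuild();
      u.ones(); v.ones();
    }
  }
  arma::mat T = K;
  T.each_col() %= u;
  T.each_row() %= v.t();
  for (arma::uword i = 0; i < n; ++i)
    f(i) += lam * std::log(std::max(u(i), xmin));
  for (arma::uword j = 0; j < m; ++j)
    g(j) += lam * std::log(std::max(v(j), xmin));
  return Rcpp::List::create(Rcpp::Named("matrix") = T,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("f") = f, Rcpp::Named("g") = g);
}
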