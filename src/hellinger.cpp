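#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Pairwise matrix-Hellinger Gram matrix from precomputed symmetric square
// roots.  S is a d x d x N cube whose i'th slice is P_i^{1/2}; tr holds the
// traces of the P_i.  Uses
//   d_H(A,B)^2 = tr(A) + tr(B) - 2 ||S_A S_B||_*
// where ||.||_* is the nuclear norm: A^{1/2} B A^{1/2} = (S_A S_B)(S_A S_B)^T,
// so tr[(A^{1/2} B A^{1/2})^{1/2}] equals the sum of singular values of
// S_A S_B, computed from the eigenvalues of the symmetric matrix M^T M.
// [[Rcpp::export]]
arma::mat hellinger_gram_cpp(const arma::cube& S, const arma::vec& tr) {
  const arma::uword N = S.n_slices;
  arma::mat D(N, N, arma::fill::zeros);
  arma::mat M, MtM;
  arma::vec ev;
  for (arma::uword i = 0; i + 1 < N; ++i) {
    for (arma::uword j = i + 1; j < N; ++j) {
      M = S.slice(i) * S.slice(j);
      MtM = M.t() * M;
      arma::eig_sym(ev, MtM);
      double nuc = 0.0;
      for (arma::uword k = 0; k < ev.n_elem; ++k)
        nuc += std::sqrt(ev(k) > 0.0 ? ev(k) : 0.0);
      double v = tr(i) + tr(j) - 2.0 * nuc;
      if (v < 0.0) v = 0.0;  // numerical clamp; exact value is >= 0
      double h = std::sqrt(v);
      D(i, j) = h;
      D(j, i) = h;
    }
  }
  return D;
}
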