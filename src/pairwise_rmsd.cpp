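// Pairwise best-fit RMSD matrix over an ensemble.
//
// For each pair of frames the weighted Kabsch superposition is solved in
// closed form: after centering, rmsd^2 = (Sx + Sy - 2*(s1 + s2 +/- s3)) / W
// where s_k are the singular values of the weighted cross-covariance and the
// sign of s3 corrects improper rotations. Only the 3x3 SVD depends on the
// pair, so the F x F matrix costs O(F^2 * (9N + svd3)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
NumericMatrix pairwise_rmsd_cpp(NumericVector coords, IntegerVector sel,
                                NumericVector weights) {
  IntegerVector dims = coords.attr("dim");
  const int N = dims[0];
  const int F = dims[2];
  const int n = sel.size();
  if (weights.size() != n) stop("weights length mismatch");

  arma::vec w(n);
  double W = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = weights[i]; W += weights[i]; }

  // centered selected coordinates per frame (n x 3 each) and self-terms
  std::vector<arma::mat> X(F);
  arma::vec self(F);
  const double* base = coords.begin();
  for (int f = 0; f < F; ++f) {
    arma::mat M(n, 3);
    const double* fr = base + static_cast<size_t>(f) * N * 3;
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < n; ++i)
        M(i, c) = fr[c * N + (sel[i] - 1)];
    arma::rowvec com = (w.t() * M) / W;
    M.each_row() -= com;
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += w[i] * arma::dot(M.row(i), M.row(i));
    X[f] = M;
    self[f] = s;
  }

  NumericMatrix out(F, F);
  arma::mat H(3, 3), U, V;
  arma::vec s;
  for (int i = 0; i < F; ++i) {
    for (int j = i + 1; j < F; ++j) {
      H = X[i].t() * (X[j].each_col() % w);
      if (!arma::svd(U, s, V, H))
        stop("SVD failed for frame pair (%d, %d)", i + 1, j + 1);
      double sgn = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
      double tr = s[0] + s[1] + sgn * s[2];
      double msd = (self[i] + self[j] - 2.0 * tr) / W;
      double r = msd > 0.0 ? std::sqrt(msd) : 0.0;
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}
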