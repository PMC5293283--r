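// All-pairs frame RMSD matrix with optional per-pair Kabsch superposition
// (proper rotation only). Frames come in as F x 3n flat rows; atoms are
// column triplets. Used by the GROMOS-style conformational clustering,
// where the full F x F matrix is the substrate of the greedy
// neighbour-count algorithm.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// reshape flat row (x1,y1,z1,...) to 3 x n (atoms as columns)
static mat row_to_coords(const rowvec& r) {
  return reshape(mat(r), 3, r.n_elem / 3);
}

// proper rotation R with R * Pc ~= Qc (atoms as columns, centred)
static mat kabsch(const mat& Pc, const mat& Qc) {
  mat H = Pc * Qc.t();
  mat U, V; vec s;
  svd(U, s, V, H);
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  return V * D * U.t();
}

// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::mat& xyz, const arma::mat& fitxyz, bool fit) {
  const uword F = xyz.n_rows;
  const uword n = xyz.n_cols / 3;
  mat out(F, F, fill::zeros);
  std::vector<mat> A(F), Afit(F);
  for (uword f = 0; f < F; ++f) {
    A[f] = row_to_coords(xyz.row(f));
    if (fit) Afit[f] = row_to_coords(fitxyz.row(f));
  }
  for (uword f = 0; f < F; ++f) {
    for (uword g = f + 1; g < F; ++g) {
      double r;
      if (fit) {
        vec cf = mean(Afit[f], 1), cg = mean(Afit[g], 1);
        mat R = kabsch(Afit[f].each_col() - cf, Afit[g].each_col() - cg);
        mat moved = R * (A[f].each_col() - cf);
        moved.each_col() += cg;
        r = std::sqrt(accu(square(moved - A[g])) / n);
      } else {
        r = std::sqrt(accu(square(A[f] - A[g])) / n);
      }
      out(f, g) = r;
      out(g, f) = r;
    }
  }
  return out;
}
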