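#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// OLS branch-length fitting on a fixed topology, encoded by the edge-by-leaf
// indicator matrix B (B[e, l] = 1 iff leaf l lies on the child side of edge e
// for an arbitrary rooting). The normal equations A'A b = A'd of the
// unweighted least-squares problem over all leaf pairs are assembled directly
// from split overlaps: (A'A)[e,f] is the number of leaf pairs whose path uses
// both edges, and (A'd)[e] is the sum of distances across edge e. The
// minimum-evolution criterion is the sum of the fitted lengths.

static bool ols_core(const arma::mat &B, const arma::mat &D,
                     arma::vec &lengths, double &total) {
  const double n = (double)B.n_cols;
  arma::mat C = B * B.t();
  arma::vec ne = arma::sum(B, 1);
  arma::mat NE = arma::repmat(ne, 1, B.n_rows);
  arma::mat ATA = C % (n - NE - NE.t() + C) + (NE - C) % (NE.t() - C);
  arma::mat M = B * D;
  arma::vec S = arma::sum(M, 1) - arma::sum(M % B, 1);
  bool ok = arma::solve(lengths, ATA, S, arma::solve_opts::no_approx);
  if (!ok) return false;
  total = arma::accu(lengths);
  return true;
}

// [[Rcpp::export]]
List ols_fit_cpp(arma::mat B, arma::mat D) {
  arma::vec lengths;
  double total = 0.0;
  if (!ols_core(B, D, lengths, total))
    stop("OLS fit: singular normal equations (degenerate topology)");
  return List::create(_["lengths"] = lengths, _["total"] = total);
}
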