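// Codon-model numerics: GY94 rate matrices, spectral transition
// probabilities, and the pruning likelihood over site patterns.
// The 61-state masks (adjacency / transition / nonsynonymous) are built
// once on the R side from the standard genetic code and passed in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// GY94 generator for one branch class, scaled to unit expected
// substitution rate at stationarity (-sum_i pi_i q_ii = 1), so branch
// lengths are expected substitutions per codon under that class's omega.
// [[Rcpp::export]]
arma::mat cpp_build_Q(double kappa, double omega, const arma::vec& pi,
                      const arma::mat& adj, const arma::mat& ts,
                      const arma::mat& nonsyn) {
  mat Q = adj % (1.0 + (kappa - 1.0) * ts) % (1.0 + (omega - 1.0) * nonsyn);
  Q.each_row() %= pi.t();          // target-frequency parameterization
  Q.diag().zeros();
  Q.diag() = -sum(Q, 1);
  double rate = -dot(pi, Q.diag());
  if (rate > 0.0) Q /= rate;
  return Q;
}

// Spectral decomposition of a reversible Q via the pi-symmetrized form
// S = D^{1/2} Q D^{-1/2}; returns left/right factors so that
// P(t) = left * diag(exp(lambda t)) * right.
// [[Rcpp::export]]
Rcpp::List cpp_eigen_system(const arma::mat& Q, const arma::vec& pi) {
  vec sq = sqrt(pi);
  mat S = Q;
  S.each_col() %= sq;
  S.each_row() /= sq.t();
  S = 0.5 * (S + S.t());           // enforce exact symmetry
  vec lambda;
  mat V;
  eig_sym(lambda, V, S);
  mat left = V;
  left.each_col() /= sq;
  mat right = V.t();
  right.each_row() %= sq.t();
  return Rcpp::List::create(Rcpp::Named("left") = left,
                            Rcpp::Named("right") = right,
                            Rcpp::Named("values") = lambda);
}

// [[Rcpp::export]]
arma::mat cpp_transition(const arma::mat& left, const arma::mat& right,
                         const arma::vec& lambda, double t) {
  mat P = left * diagmat(exp(lambda * t)) * right;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Per-pattern log-likelihood by postorder pruning.
// tipstate: ntip x npat, 0-based state index, -1 = missing (uniform
// partial likelihood over all states). edge: nedge x 2 (parent, child),
// 0-based node ids, tips 0..ntip-1, ordered so every child row precedes
// the rows where that node is a parent (ape postorder). P: list of
// transition matrices, one per edge row.
// [[Rcpp::export]]
arma::vec cpp_pattern_loglik(const arma::imat& tipstate,
                             const arma::imat& edge,
                             const Rcpp::List& P,
                             const arma::vec& pi) {
  const int ntip = tipstate.n_rows;
  const int npat = tipstate.n_cols;
  const int nedge = edge.n_rows;
  const int nnode = nedge + 1;
  const int ns = pi.n_elem;

  std::vector<mat> part(nnode);
  std::vector<bool> seen(nnode, false);
  vec scale(npat, fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    mat contrib;
    if (ch < ntip) {
      // fold the tip's indicator partials directly into P columns
      contrib.set_size(ns, npat);
      const mat& Pm = Rcpp::as<mat>(P[e]);
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(ch, s);
        if (st < 0)
          contrib.col(s) = sum(Pm, 1);
        else
          contrib.col(s) = Pm.col(st);
      }
    } else {
      contrib = Rcpp::as<mat>(P[e]) * part[ch];
      part[ch].reset();
    }
    if (!seen[par]) {
      part[par] = contrib;
      seen[par] = true;
    } else {
      part[par] %= contrib;
      // rescale to keep partials in range on long trees
      rowvec m = max(part[par], 0);
      for (int s = 0; s < npat; ++s) {
        if (m(s) > 0.0 && m(s) < 1e-6) {
          part[par].col(s) /= m(s);
          scale(s) += std::log(m(s));
        }
      }
    }
  }

  int root = edge(nedge - 1, 0);
  rowvec site = pi.t() * part[root];
  vec out(npat);
  for (int s = 0; s < npat; ++s)
    out(s) = (site(s) > 0.0 ? std::log(site(s)) : -datum::inf) + scale(s);
  return out;
}
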