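// Felsenstein pruning over discrete rate categories.
// The eigendecomposition of the (reversible, normalized) rate matrix is
// passed in, so P(t) = right * diag(exp(lambda * t)) * left.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// edge: E x 2 matrix of 1-based node ids in postorder (children before
// parents); states: ntip x S, residues 1..20, 0 = missing; returns S x K
// per-site per-category log-likelihoods (root frequencies applied).
// [[Rcpp::export]]
arma::mat cpp_prune_loglik(const arma::imat& edge,
                           const arma::vec& elen,
                           const arma::imat& states,
                           const arma::mat& right,
                           const arma::mat& left,
                           const arma::vec& eigval,
                           const arma::vec& freq,
                           const arma::vec& rates,
                           int nnode) {
  const int ntip = states.n_rows;
  const int S = states.n_cols;
  const int K = rates.n_elem;
  const int E = edge.n_rows;
  arma::mat out(S, K);

  for (int k = 0; k < K; ++k) {
    std::vector<arma::mat> partial(ntip + nnode);
    std::vector<bool> has(ntip + nnode, false);
    arma::rowvec scaler(S, arma::fill::zeros);
    for (int e = 0; e < E; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      double t = elen(e) * rates(k);
      arma::mat P = right * arma::diagmat(arma::exp(eigval * t)) * left;
      P.clamp(0.0, arma::datum::inf);
      arma::mat contrib(20, S);
      if (ch < ntip) {
        // tip partials are indicators: P * partial is a column gather
        arma::vec ones20(20, arma::fill::ones);
        for (int s = 0; s < S; ++s) {
          int st = states(ch, s);
          if (st <= 0) contrib.col(s) = ones20;
          else contrib.col(s) = P.col(st - 1);
        }
      } else {
        contrib = P * partial[ch];
        partial[ch].reset();
      }
      if (!has[p]) {
        partial[p] = contrib;
        has[p] = true;
      } else {
        partial[p] %= contrib;
        arma::rowvec mx = arma::max(partial[p], 0);
        mx.transform([](double x) { return x == 0.0 ? 1.0 : x; });
        scaler += arma::log(mx);
        partial[p].each_row() /= mx;
      }
    }
    arma::rowvec lik = freq.t() * partial[ntip];   // root is node ntip+1
    out.col(k) = (arma::log(lik) + scaler).t();
  }
  return out;
}
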