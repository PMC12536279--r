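// Continuous-time Markov core: matrix exponential transition probabilities
// and the Felsenstein pruning log-likelihood. Hot path of the MCMC, hence C++.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// exp(Q t) via Armadillo's scaling-and-squaring Pade implementation
// [[Rcpp::export]]
arma::mat expm_ctm(const arma::mat& Q, double t) {
  if (t < 0) stop("branch length must be non-negative");
  if (t == 0) return arma::eye(Q.n_rows, Q.n_cols);
  return arma::expmat(Q * t);
}

// Pruning log-likelihood on one tree.
//   edge        : Nedge x 2 integer matrix (parent, child), 1-based node ids,
//                 tips 1..n, in POSTORDER (children before parents)
//   edge_length : branch lengths, same order
//   tip_partial : n x k matrix of 0/1 tip partial likelihoods (ambiguity sets
//                 put 1 on each allowed state; missing data = all 1)
//   Q           : k x k generator
//   root_prior  : length-k probability vector
//   n_internal  : number of internal nodes
//   root        : 1-based id of the root node
// Per-node rescaling keeps partials in range; log scale factors accumulate.
// [[Rcpp::export]]
double prune_loglik_cpp(const arma::imat& edge,
                        const arma::vec& edge_length,
                        const arma::mat& tip_partial,
                        const arma::mat& Q,
                        const arma::vec& root_prior,
                        int n_internal,
                        int root) {
  const int n_tips = tip_partial.n_rows;
  const int k = Q.n_rows;
  const int n_total = n_tips + n_internal;
  arma::mat partial(n_total, k);
  partial.rows(0, n_tips - 1) = tip_partial;
  partial.rows(n_tips, n_total - 1).ones();

  double log_scale = 0.0;
  const arma::uword n_edge = edge.n_rows;
  for (arma::uword e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    arma::rowvec child_part = partial.row(child);
    const double m = child_part.max();
    if (m <= 0.0) return R_NegInf;
    child_part /= m;
    log_scale += std::log(m);
    arma::mat P = (edge_length(e) == 0.0)
      ? arma::eye(k, k)
      : arma::mat(arma::expmat(Q * edge_length(e)));
    if (!P.is_finite()) return R_NaN;  // ||Qt|| too large for expmat
    partial.row(parent) %= (P * child_part.t()).t();
  }
  const double lik = arma::dot(root_prior, partial.row(root - 1).t());
  if (std::isnan(lik)) return R_NaN;
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + log_scale;
}

// Pruning partials for the ancestral-state up-pass: returns the (rescaled)
// partial-likelihood matrix for all nodes plus per-edge transition matrices
// are recomputed in R where needed; this returns raw partials with per-node
// log scale factors so downstream code can renormalize.
// [[Rcpp::export]]
List prune_partials_cpp(const arma::imat& edge,
                        const arma::vec& edge_length,
                        const arma::mat& tip_partial,
                        const arma::mat& Q,
                        int n_internal) {
  const int n_tips = tip_partial.n_rows;
  const int k = Q.n_rows;
  const int n_total = n_tips + n_internal;
  arma::mat partial(n_total, k);
  partial.rows(0, n_tips - 1) = tip_partial;
  partial.rows(n_tips, n_total - 1).ones();
  arma::vec log_scale(n_total, arma::fill::zeros);

  const arma::uword n_edge = edge.n_rows;
  for (arma::uword e = 0; e < n_edge; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    arma::rowvec child_part = partial.row(child);
    const double m = child_part.max();
    if (m <= 0.0) stop("zero partial likelihood during up-pass");
    child_part /= m;
    partial.row(child) = child_part;  // store rescaled
    log_scale(child) += std::log(m);
    log_scale(parent) += log_scale(child);
    arma::mat P = (edge_length(e) == 0.0)
      ? arma::eye(k, k)
      : arma::mat(arma::expmat(Q * edge_length(e)));
    partial.row(parent) %= (P * child_part.t()).t();
  }
  return List::create(_["partial"] = partial, _["log_scale"] = log_scale);
}
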