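// Felsenstein pruning over site patterns for a reversible 20-state model,
// with per-pattern log scaling to avoid underflow on larger trees.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Transition matrix P(t) = U diag(exp(eva * t)) Uinv for the symmetrized
// eigen-decomposition of Q.
static mat pmat(const mat& U, const mat& Uinv, const vec& eva, double t) {
  vec e = exp(eva * t);
  mat P = U * diagmat(e) * Uinv;
  // clamp tiny negative round-off
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// Per-pattern log-likelihood for each rate category.
//
// edge: (parent, child) rows in postorder (children processed before their
//       parent); 1-based ape node numbering, root = n_tip + 1.
// tip_states: n_pattern x n_tip, values 1..20, 0 = missing (X).
// el: branch length per edge row (expected substitutions/site at rate 1).
// rates: relative rate of each mixture category.
// Returns n_pattern x n_category matrix of log site likelihoods
// log sum_s pi_s L_s(root).
// [[Rcpp::export]]
arma::mat pruning_loglik_cpp(const arma::imat& edge, int n_tip,
                             const arma::imat& tip_states,
                             const arma::vec& el,
                             const arma::mat& U, const arma::mat& Uinv,
                             const arma::vec& eva, const arma::vec& pi,
                             const arma::vec& rates, int root) {
  const int n_pat = tip_states.n_rows;
  const int n_state = pi.n_elem;
  const int n_edge = edge.n_rows;
  const int K = rates.n_elem;
  const int n_alloc = edge.max();
  mat out(n_pat, K);

  for (int k = 0; k < K; ++k) {
    std::vector<mat> part(n_alloc + 1);  // state x pattern partials per node
    vec logscale(n_pat, fill::zeros);
    for (int e = 0; e < n_edge; ++e) {
      int par = edge(e, 0), chi = edge(e, 1);
      mat P = pmat(U, Uinv, eva, el(e) * rates(k));
      mat contrib(n_state, n_pat);
      if (chi <= n_tip) {
        for (int p = 0; p < n_pat; ++p) {
          int s = tip_states(p, chi - 1);
          if (s == 0)
            contrib.col(p) = sum(P, 1);  // missing tip: row sums (= 1)
          else
            contrib.col(p) = P.col(s - 1);
        }
      } else {
        // rescale the completed child partial before propagating
        mat& cp = part[chi];
        for (int p = 0; p < n_pat; ++p) {
          double m = cp.col(p).max();
          if (m > 0.0 && m != 1.0) {
            cp.col(p) /= m;
            logscale(p) += std::log(m);
          }
        }
        contrib = P * cp;
        cp.reset();
      }
      if (part[par].n_elem == 0)
        part[par] = contrib;
      else
        part[par] %= contrib;
    }
    mat& rp = part[root];
    for (int p = 0; p < n_pat; ++p) {
      double L = dot(pi, rp.col(p));
      out(p, k) = (L > 0 ? std::log(L) : -1e300) + logscale(p);
    }
  }
  return out;
}
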