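// Core numerics for the 4-state correlated-evolution model: CTMC transition
// probabilities and the Felsenstein pruning recursion with per-node rescaling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Eigen-decomposition cache for one Q: P(t) = Re(V exp(D t) V^-1) when V is
// well-conditioned, otherwise scaling-and-squaring Pade (arma::expmat).
struct ExpmCache {
  mat Q;
  bool use_eigen = false;
  cx_vec eigval;
  cx_mat V;
  cx_mat Vinv;

  explicit ExpmCache(const mat& Q_) : Q(Q_) {
    cx_mat V_;
    cx_vec ev;
    bool ok = eig_gen(ev, V_, Q);
    if (ok && V_.is_finite()) {
      double c = cond(V_);
      if (std::isfinite(c) && c < 1e8) {
        eigval = ev;
        V = V_;
        Vinv = inv(V_);
        use_eigen = Vinv.is_finite();
      }
    }
  }

  mat P(double t) const {
    mat out;
    if (use_eigen) {
      cx_vec e = exp(eigval * t);
      cx_mat M = V * diagmat(e) * Vinv;
      out = real(M);
    } else {
      out = expmat(Q * t);
    }
    // roundoff can leave tiny negatives; probabilities live in [0, 1]
    out.clamp(0.0, 1.0);
    return out;
  }
};

// [[Rcpp::export(name = ".expm_ctmc_cpp")]]
arma::mat expm_ctmc_cpp(const arma::mat& Q, double t) {
  ExpmCache cache(Q);
  return cache.P(t);
}

// Pruning pass. edge: 2-column matrix of 1-based node ids in postorder
// (children complete before their parent edge). tip_partials: nstate x ntip,
// one-hot for observed tips, all ones for unknown. Returns the log partial
// likelihoods at the root, one per state.
// [[Rcpp::export(name = ".root_logpartials_cpp")]]
arma::vec root_logpartials_cpp(const arma::imat& edge,
                               const arma::vec& edge_length,
                               const arma::mat& tip_partials,
                               int n_node,
                               const arma::mat& Q) {
  const int nstate = Q.n_rows;
  const int ntip = tip_partials.n_cols;
  const int ntotal = ntip + n_node;
  ExpmCache cache(Q);

  mat partial(nstate, ntotal, fill::ones);
  partial.cols(0, ntip - 1) = tip_partials;
  vec logscale(ntotal, fill::zeros);

  int root = edge(0, 0) - 1;  // first postorder parent; overwritten below
  for (uword k = 0; k < edge.n_rows; ++k) {
    int p = edge(k, 0) - 1;
    int c = edge(k, 1) - 1;
    mat P = cache.P(edge_length(k));
    vec contrib = P * partial.col(c);
    partial.col(p) %= contrib;
    logscale(p) += logscale(c);
    double m = partial.col(p).max();
    if (m <= 0.0 || !std::isfinite(m)) {
      vec out(nstate);
      out.fill(-datum::inf);
      return out;
    }
    partial.col(p) /= m;
    logscale(p) += std::log(m);
    root = p;
  }
  // the last postorder edge's parent is the root
  vec lp(nstate);
  for (int s = 0; s < nstate; ++s) {
    double v = partial(s, root);
    lp(s) = (v > 0.0) ? std::log(v) + logscale(root) : -datum::inf;
  }
  return lp;
}
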