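// Pruning likelihood and MH sweep for affinity-set models with cladogenetic
// transitions.
//
// Node partials D(node)_i = P(tip data below node | state i at the node,
// pre-cladogenesis). Branch partials F(edge)_j = sum_j' expm(Q t)_{j j'}
// D(child)_{j'}, with j the corner state at the branch start. At an internal
// node, D(node)_i = sum_{(i;j,k)} P(i;j,k) F(left)_j F(right)_k over the
// sparse cladogenetic tensor. The root is combined the same way and dotted
// with the root state frequencies. Per-node rescaling accumulates log
// scalers to avoid underflow on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct TreeIdx {
  arma::imat edge;          // 0-based (parent, child)
  arma::vec edge_length;
  arma::ivec postorder;     // 0-based edge indices
  std::vector<int> child_edge1, child_edge2;  // per node, 0-based
  int n_tips, n_nodes, root;
};

TreeIdx make_tree(const IntegerMatrix& edge, const NumericVector& edge_length,
                  const IntegerVector& postorder, int n_tips) {
  TreeIdx tr;
  const int n_edges = edge.nrow();
  tr.edge.set_size(n_edges, 2);
  for (int e = 0; e < n_edges; ++e) {
    tr.edge(e, 0) = edge(e, 0) - 1;
    tr.edge(e, 1) = edge(e, 1) - 1;
  }
  tr.edge_length = as<arma::vec>(edge_length);
  tr.postorder.set_size(n_edges);
  for (int i = 0; i < n_edges; ++i) tr.postorder[i] = postorder[i] - 1;
  tr.n_tips = n_tips;
  tr.n_nodes = 2 * n_tips - 1;
  tr.root = n_tips;  // 0-based
  tr.child_edge1.assign(tr.n_nodes, -1);
  tr.child_edge2.assign(tr.n_nodes, -1);
  for (int e = 0; e < n_edges; ++e) {
    int p = tr.edge(e, 0);
    if (tr.child_edge1[p] < 0) tr.child_edge1[p] = e;
    else tr.child_edge2[p] = e;
  }
  return tr;
}

struct Tensor {
  arma::ivec parent, left, right, scenario;  // 0-based states; scenario 1..3
  arma::vec denom;
  arma::uvec forced;
  arma::vec prob;
  void set_prob(double pe, double ps, double pb) {
    for (arma::uword k = 0; k < parent.n_elem; ++k) {
      double num = scenario[k] == 1 ? pe : (scenario[k] == 2 ? ps : pb);
      prob[k] = forced[k] ? 1.0 : num / denom[k];
    }
  }
};

// transition matrices for all edges; eigendecomposition when Q is safely
// diagonalizable, scaling-and-squaring otherwise
void edge_pt(const arma::mat& Q, const arma::vec& len, arma::cube& out) {
  const int S = Q.n_rows, n_edges = len.n_elem;
  out.set_size(S, S, n_edges);
  arma::cx_vec eval;
  arma::cx_mat evec, vinv;
  bool ok = arma::eig_gen(eval, evec, Q) && arma::inv(vinv, evec);
  if (ok) {
    arma::mat recon = arma::real(evec * arma::diagmat(eval) * vinv);
    ok = arma::abs(recon - Q).max() <= 1e-9 * (1.0 + arma::abs(Q).max());
  }
  if (ok) {
    for (int e = 0; e < n_edges; ++e) {
      arma::mat P = arma::real(evec * arma::diagmat(arma::exp(eval * len[e]))
                                 * vinv);
      P.transform([](double x) { return x < 0 ? 0.0 : x; });
      out.slice(e) = P;
    }
  } else {
    for (int e = 0; e < n_edges; ++e)
      out.slice(e) = arma::expmat(Q * len[e]);
  }
}

// core pruning pass over precomputed per-edge transition matrices;
// D and F are caller-owned workspaces (S x n_nodes, S x n_edges)
double prune_core(const TreeIdx& tr, const arma::cube& Pt,
                  const arma::mat& tip_partials, const Tensor& tensor,
                  const arma::vec& root_freq, bool rescale,
                  arma::mat& D, arma::mat& F, int* bad_node) {
  const int S = root_freq.n_elem;
  for (int t = 0; t < tr.n_tips; ++t) D.col(t) = tip_partials.col(t);
  double log_scale = 0.0;
  int bad = -1;
  const int n_entries = tensor.parent.n_elem;

  auto combine = [&](int node) {
    double* d = D.colptr(node);
    std::fill(d, d + S, 0.0);
    const double* fl = F.colptr(tr.child_edge1[node]);
    const double* fr = F.colptr(tr.child_edge2[node]);
    for (int k = 0; k < n_entries; ++k)
      d[tensor.parent[k]] += tensor.prob[k] * fl[tensor.left[k]] *
        fr[tensor.right[k]];
    double mx = *std::max_element(d, d + S);
    if (mx <= 0) { if (bad < 0) bad = node; }
    else if (rescale) {
      for (int i = 0; i < S; ++i) d[i] /= mx;
      log_scale += std::log(mx);
    }
  };

  for (arma::uword idx = 0; idx < tr.postorder.n_elem; ++idx) {
    int e = tr.postorder[idx];
    int child = tr.edge(e, 1);
    if (child >= tr.n_tips) combine(child);
    F.col(e) = Pt.slice(e) * D.col(child);
    if (rescale) {
      double mx = F.col(e).max();
      if (mx > 0) { F.col(e) /= mx; log_scale += std::log(mx); }
    }
  }
  combine(tr.root);

  if (bad_node) *bad_node = bad;
  double lik = arma::dot(root_freq, D.col(tr.root));
  return (bad >= 0 || lik <= 0) ? R_NegInf : std::log(lik) + log_scale;
}

Tensor make_tensor(const IntegerVector& parent, const IntegerVector& left,
                   const IntegerVector& right, const IntegerVector& scenario,
                   const NumericVector& denom, const LogicalVector& forced) {
  Tensor t;
  const int n = parent.size();
  t.parent.set_size(n); t.left.set_size(n); t.right.set_size(n);
  t.scenario.set_size(n); t.denom.set_size(n); t.forced.set_size(n);
  t.prob.set_size(n);
  for (int k = 0; k < n; ++k) {
    t.parent[k] = parent[k] - 1;
    t.left[k] = left[k] - 1;
    t.right[k] = right[k] - 1;
    t.scenario[k] = scenario[k];
    t.denom[k] = denom[k];
    t.forced[k] = forced[k] ? 1 : 0;
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
List cpp_prune(const arma::mat& Q,
               const IntegerMatrix& edge,
               const NumericVector& edge_length,
               const IntegerVector& postorder,
               const arma::mat& tip_partials,
               const IntegerVector& tensor_parent,
               const IntegerVector& tensor_left,
               const IntegerVector& tensor_right,
               const NumericVector& tensor_prob,
               const arma::vec& root_freq,
               const int n_tips,
               const bool rescale,
               const bool return_partials) {
  TreeIdx tr = make_tree(edge, edge_length, postorder, n_tips);
  Tensor tensor;
  const int n = tensor_parent.size();
  tensor.parent.set_size(n); tensor.left.set_size(n); tensor.right.set_size(n);
  tensor.prob.set_size(n);
  for (int k = 0; k < n; ++k) {
    tensor.parent[k] = tensor_parent[k] - 1;
    tensor.left[k] = tensor_left[k] - 1;
    tensor.right[k] = tensor_right[k] - 1;
    tensor.prob[k] = tensor_prob[k];
  }
  arma::cube Pt;
  edge_pt(Q, tr.edge_length, Pt);
  arma::mat D(Q.n_rows, tr.n_nodes), F(Q.n_rows, tr.edge.n_rows);
  int bad = -1;
  double loglik = prune_core(tr, Pt, tip_partials, tensor, root_freq, rescale,
                             D, F, &bad);
  List out = List::create(_["loglik"] = loglik,
                          _["impossible_node"] =
                            bad >= 0 ? IntegerVector::create(bad + 1)
                                     : IntegerVector::create(NA_INTEGER));
  if (return_partials) {
    out["D"] = D;
    out["F"] = F;
    out["Pt"] = Pt;
  }
  return out;
}

// Metropolis-Hastings sweep: the anagenetic rates (exponential prior, scale
// prior_beta) then ps and pb (uniform, simplex constraint through the prior),
// each with a multiplier proposal x' = x exp(lambda * unif(-0.5, 0.5)).
// Transition matrices are cached and rebuilt only when a rate move is
// accepted. Uses R's RNG, so seeds set in R apply.
// [[Rcpp::export]]
List cpp_mcmc(const IntegerVector& qt_i,      // Q template rows (1-based)
              const IntegerVector& qt_j,
              const IntegerVector& qt_rate,   // rate index per entry, 1-based
              const NumericVector& rate_init,
              const double ps_init, const double pb_init,
              const IntegerVector& tensor_parent,
              const IntegerVector& tensor_left,
              const IntegerVector& tensor_right,
              const IntegerVector& tensor_scenario,
              const NumericVector& tensor_denom,
              const LogicalVector& tensor_forced,
              const IntegerMatrix& edge,
              const NumericVector& edge_length,
              const IntegerVector& postorder,
              const arma::mat& tip_partials,
              const arma::vec& root_freq,
              const int n_tips,
              const double prior_beta,
              const int iterations, const int thin,
              const double lambda_rates, const double lambda_clado,
              const int burn_iter, const int ancestral_every) {
  TreeIdx tr = make_tree(edge, edge_length, postorder, n_tips);
  Tensor tensor = make_tensor(tensor_parent, tensor_left, tensor_right,
                              tensor_scenario, tensor_denom, tensor_forced);
  const int S = root_freq.n_elem;
  const int n_rates = rate_init.size();

  arma::vec rates = as<arma::vec>(rate_init);
  double ps = ps_init, pb = pb_init;
  auto fill_q = [&](const arma::vec& r) {
    arma::mat Q(S, S, arma::fill::zeros);
    for (int k = 0; k < qt_i.size(); ++k)
      Q(qt_i[k] - 1, qt_j[k] - 1) = r[qt_rate[k] - 1];
    Q.diag() = -arma::sum(Q, 1);
    return Q;
  };
  auto log_prior = [&](const arma::vec& r, double ps_, double pb_) {
    if (ps_ <= 0 || ps_ >= 1 || pb_ <= 0 || pb_ >= 1 || ps_ + pb_ > 1)
      return R_NegInf;
    return -n_rates * std::log(prior_beta) - arma::accu(r) / prior_beta;
  };

  arma::cube Pt, Pt_new;
  arma::mat Dw(S, tr.n_nodes), Fw(S, tr.edge.n_rows);  // workspaces
  arma::vec prob_old(tensor.prob.n_elem);
  edge_pt(fill_q(rates), tr.edge_length, Pt);
  tensor.set_prob(1 - ps - pb, ps, pb);
  double ll = prune_core(tr, Pt, tip_partials, tensor, root_freq, true,
                         Dw, Fw, nullptr);
  double lp = log_prior(rates, ps, pb);
  if (!std::isfinite(ll))
    return List::create(_["error"] = "initial likelihood is not finite");

  const int n_par = n_rates + 2;
  const int n_keep = iterations / thin;
  arma::mat trace(n_keep, n_par + 4);
  arma::vec accept(n_par, arma::fill::zeros);
  std::vector<arma::vec> snapshots;
  int row = 0;

  for (int iter = 1; iter <= iterations; ++iter) {
    for (int j = 0; j < n_par; ++j) {
      const bool is_rate = j < n_rates;
      const double lam = is_rate ? lambda_rates : lambda_clado;
      const double u = R::runif(-0.5, 0.5);
      const double log_hastings = lam * u;
      const double mult = std::exp(log_hastings);
      if (is_rate) {
        arma::vec r_new = rates;
        r_new[j] *= mult;
        double lp_new = log_prior(r_new, ps, pb);
        edge_pt(fill_q(r_new), tr.edge_length, Pt_new);
        double ll_new = prune_core(tr, Pt_new, tip_partials, tensor,
                                   root_freq, true, Dw, Fw, nullptr);
        if (std::log(R::runif(0, 1)) < ll_new + lp_new - ll - lp +
              log_hastings) {
          rates = r_new; ll = ll_new; lp = lp_new;
          std::swap(Pt, Pt_new);
          accept[j] += 1;
        }
      } else {
        double ps_new = j == n_rates ? ps * mult : ps;
        double pb_new = j == n_rates ? pb : pb * mult;
        double lp_new = log_prior(rates, ps_new, pb_new);
        if (std::isfinite(lp_new)) {
          prob_old = tensor.prob;
          tensor.set_prob(1 - ps_new - pb_new, ps_new, pb_new);
          double ll_new = prune_core(tr, Pt, tip_partials, tensor, root_freq,
                                     true, Dw, Fw, nullptr);
          if (std::log(R::runif(0, 1)) < ll_new + lp_new - ll - lp +
                log_hastings) {
            ps = ps_new; pb = pb_new; ll = ll_new; lp = lp_new;
            accept[j] += 1;
          } else {
            tensor.prob = prob_old;
          }
        }
      }
    }
    if (iter % thin == 0) {
      trace(row, 0) = iter;
      for (int k = 0; k < n_rates; ++k) trace(row, 1 + k) = rates[k];
      trace(row, n_rates + 1) = ps;
      trace(row, n_rates + 2) = pb;
      trace(row, n_rates + 3) = 1 - ps - pb;
      trace(row, n_par + 2) = ll;
      trace(row, n_par + 3) = lp;
      ++row;
    }
    if (ancestral_every > 0 && iter > burn_iter &&
        (iter - burn_iter) % ancestral_every == 0) {
      arma::vec snap(n_rates + 2);
      snap.head(n_rates) = rates;
      snap[n_rates] = ps;
      snap[n_rates + 1] = pb;
      snapshots.push_back(snap);
    }
  }

  arma::mat snap_mat(snapshots.size(), n_rates + 2);
  for (size_t s = 0; s < snapshots.size(); ++s)
    snap_mat.row(s) = snapshots[s].t();
  return List::create(_["trace"] = trace, _["accept"] = accept,
                      _["snapshots"] = snap_mat);
}
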