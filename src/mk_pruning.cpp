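#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for the symmetric 2-state Mk (ER) model with a flat
// (1/2, 1/2) root prior. Edge transition probabilities:
//   P(stay)   = (1 + exp(-2 q t)) / 2
//   P(switch) = (1 - exp(-2 q t)) / 2
//
// `edge` is the tree's edge matrix in postorder (1-based node ids, tips
// 1..ntip), `elen` the matching edge lengths. `tip_state` holds 0, 1, or -1
// (missing; partial likelihood (1,1)). Returns the log-likelihood, -Inf when
// the data have probability zero (possible only at q = 0 with discordant
// tips).

// [[Rcpp::export]]
double mk_pruning_loglik(IntegerMatrix edge, NumericVector elen, int ntip,
                         int nnode, IntegerVector tip_state, double q) {
  int ntot = ntip + nnode;
  std::vector<double> L0(ntot, 1.0), L1(ntot, 1.0);
  for (int i = 0; i < ntip; ++i) {
    if (tip_state[i] == 0) { L0[i] = 1.0; L1[i] = 0.0; }
    else if (tip_state[i] == 1) { L0[i] = 0.0; L1[i] = 1.0; }
    // -1: missing, keep (1, 1)
  }
  double logscale = 0.0;
  int root = edge(edge.nrow() - 1, 0) - 1;  // postorder: root edges last
  for (int e = 0; e < edge.nrow(); ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double ex = std::exp(-2.0 * q * elen[e]);
    double pstay = 0.5 * (1.0 + ex), pswit = 0.5 * (1.0 - ex);
    double c0 = pstay * L0[c] + pswit * L1[c];
    double c1 = pswit * L0[c] + pstay * L1[c];
    L0[p] *= c0;
    L1[p] *= c1;
    double m = std::max(L0[p], L1[p]);
    if (m > 0.0 && m < 1e-100) {
      L0[p] /= m; L1[p] /= m;
      logscale += std::log(m);
    }
  }
  double lik = 0.5 * (L0[root] + L1[root]);
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}
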