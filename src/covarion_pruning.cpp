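#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for the 4-state binary covarion on a rooted time tree.
//
// Tree encoding: nodes 1..nTip are tips, nTip+1..nNode internal; `parent`
// gives each node's parent (0 for the root); `ages` are node ages. The
// branch above node i has duration ages[parent[i]] - ages[i], multiplied by
// the clock rate, the per-branch rate multiplier and the per-character-class
// (partition) multiplier. Transition matrices come from the generator's
// eigendecomposition (eval, V, Vinv). Tip states: 0/1 observed visible
// state, NA = missing (all-ones partial). Per-node rescaling guards against
// underflow on large matrices.
//
// Returns one log-likelihood per character.
// [[Rcpp::export(name = ".covarionPruning")]]
NumericVector covarion_pruning(IntegerVector parent, NumericVector ages,
    int nTip, NumericVector edgeRateMult, double meanRate,
    IntegerMatrix tipStates, IntegerVector classOfChar,
    NumericVector classRate, NumericVector eval, NumericMatrix V,
    NumericMatrix Vinv, NumericVector rootFreq) {
  const int nNode = parent.size();
  const int nChar = tipStates.ncol();
  const int nClass = classRate.size();

  // children lists and postorder
  std::vector<std::vector<int> > child(nNode);
  int root = -1;
  for (int i = 0; i < nNode; ++i) {
    if (parent[i] == 0) root = i;
    else child[parent[i] - 1].push_back(i);
  }
  std::vector<int> post;
  post.reserve(nNode);
  {
    std::vector<int> stack;
    std::vector<int> order;
    stack.push_back(root);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      order.push_back(nd);
      for (size_t k = 0; k < child[nd].size(); ++k)
        stack.push_back(child[nd][k]);
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) post.push_back(order[i]);
  }

  // per-class, per-node transition matrices P (row-major 16 doubles)
  std::vector<double> P((size_t)nClass * nNode * 16, 0.0);
  for (int c = 0; c < nClass; ++c) {
    for (int i = 0; i < nNode; ++i) {
      if (i == root) continue;
      double t = (ages[parent[i] - 1] - ages[i]) * meanRate *
        edgeRateMult[i] * classRate[c];
      if (t < 0) t = 0;
      double ev[4];
      for (int k = 0; k < 4; ++k) ev[k] = std::exp(eval[k] * t);
      double *p = &P[((size_t)c * nNode + i) * 16];
      for (int r = 0; r < 4; ++r)
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int k = 0; k < 4; ++k) acc += V(r, k) * ev[k] * Vinv(k, s);
          p[r * 4 + s] = acc > 0.0 ? acc : 0.0;
        }
    }
  }

  NumericVector out(nChar);
  std::vector<double> partial((size_t)nNode * 4);
  for (int ch = 0; ch < nChar; ++ch) {
    int c = classOfChar[ch] - 1;
    double logScale = 0.0;
    // tip partials
    for (int i = 0; i < nTip; ++i) {
      double *q = &partial[(size_t)i * 4];
      int st = tipStates(i, ch);
      if (st == NA_INTEGER) { q[0] = q[1] = q[2] = q[3] = 1.0; }
      else if (st == 0) { q[0] = 1.0; q[1] = 0.0; q[2] = 1.0; q[3] = 0.0; }
      else { q[0] = 0.0; q[1] = 1.0; q[2] = 0.0; q[3] = 1.0; }
    }
    for (int i = nTip; i < nNode; ++i) {
      double *q = &partial[(size_t)i * 4];
      q[0] = q[1] = q[2] = q[3] = 1.0;
    }
    // postorder combine: parent partial *= P_child %*% child partial
    bool dead = false;
    for (size_t k = 0; k < post.size() && !dead; ++k) {
      int nd = post[k];
      if (nd == root) continue;
      const double *p = &P[((size_t)c * nNode + nd) * 16];
      const double *q = &partial[(size_t)nd * 4];
      double *qp = &partial[(size_t)(parent[nd] - 1) * 4];
      double v[4];
      for (int r = 0; r < 4; ++r)
        v[r] = p[r * 4] * q[0] + p[r * 4 + 1] * q[1] +
          p[r * 4 + 2] * q[2] + p[r * 4 + 3] * q[3];
      double mx = 0.0;
      for (int r = 0; r < 4; ++r) { qp[r] *= v[r]; if (qp[r] > mx) mx = qp[r]; }
      if (mx <= 0.0) { dead = true; break; }
      if (mx < 1e-150) {  // rescale only when underflow threatens
        for (int r = 0; r < 4; ++r) qp[r] /= mx;
        logScale += std::log(mx);
      }
    }
    if (dead) { out[ch] = R_NegInf; continue; }
    const double *qr = &partial[(size_t)root * 4];
    double lik = 0.0;
    for (int r = 0; r < 4; ++r) lik += rootFreq[r] * qr[r];
    out[ch] = lik > 0.0 ? std::log(lik) + logScale : R_NegInf;
  }
  return out;
}
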