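#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Multivariate regression tree core. The response Y is a (sites x species)
// matrix (normally Hellinger-transformed), X a (sites x variables) constraint
// matrix. Splits are axis-parallel thresholds at midpoints between adjacent
// distinct sorted constraint values; the split maximizing the reduction in
// within-node sum of squares (summed over species) is chosen. Ties are broken
// by variable order, then by smaller threshold (first found wins because
// variables and thresholds are scanned in ascending order with a strict ">"
// comparison).

struct SplitResult {
  bool found;
  int var;          // 0-based column of X
  double threshold;
  double gain;
  double ss_left, ss_right;
};

struct Node {
  std::vector<int> members;     // row indices into Y / X
  double ss;                    // within-node sum of squares
  std::vector<double> centroid; // per-species mean
  int left, right;              // child node ids, -1 if leaf
  int split_var;                // -1 if leaf
  double threshold;
  SplitResult best;             // cached best admissible split
};

static void node_stats(const NumericMatrix& Y, const std::vector<int>& m,
                       std::vector<double>& centroid, double& ss) {
  int p = Y.ncol(), n = (int)m.size();
  centroid.assign(p, 0.0);
  for (int i : m)
    for (int j = 0; j < p; ++j) centroid[j] += Y(i, j);
  for (int j = 0; j < p; ++j) centroid[j] /= n;
  ss = 0.0;
  for (int i : m)
    for (int j = 0; j < p; ++j) {
      double d = Y(i, j) - centroid[j];
      ss += d * d;
    }
}

// Best split over all variables/thresholds for one node, via cumulative sums
// along each variable's sort order: SSE_left(k) = sum_{i<=k} ||y_i||^2 -
// sum_j (cumsum_j(k))^2 / k, and symmetrically for the right part.
static SplitResult best_split(const NumericMatrix& Y, const NumericMatrix& X,
                              const Node& nd, int min_split, double gain_tol) {
  SplitResult best; best.found = false; best.gain = -1.0;
  int n = (int)nd.members.size(), p = Y.ncol(), nv = X.ncol();
  if (n < min_split || n < 2) return best;

  std::vector<double> sqnorm(n);        // ||y_i||^2 in sorted order (filled per var)
  std::vector<int> ord(n);
  std::vector<double> xv(n);
  std::vector<double> cum(p);

  // totals are order-independent
  double tot_sq = 0.0;
  std::vector<double> tot(p, 0.0);
  for (int i : nd.members) {
    for (int j = 0; j < p; ++j) {
      double y = Y(i, j);
      tot[j] += y; tot_sq += y * y;
    }
  }

  for (int v = 0; v < nv; ++v) {
    for (int k = 0; k < n; ++k) { ord[k] = k; xv[k] = X(nd.members[k], v); }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    if (xv[ord[0]] == xv[ord[n - 1]]) continue;  // constant variable

    std::fill(cum.begin(), cum.end(), 0.0);
    double cum_sq = 0.0, cum_sumsq = 0.0; // cum_sumsq = sum_j cum_j^2 kept incrementally
    for (int k = 0; k < n - 1; ++k) {
      int row = nd.members[ord[k]];
      for (int j = 0; j < p; ++j) {
        double y = Y(row, j);
        cum_sumsq += y * (2.0 * cum[j] + y);
        cum[j] += y;
        cum_sq += y * y;
      }
      double xa = xv[ord[k]], xb = xv[ord[k + 1]];
      if (xa == xb) continue;                   // can't cut inside ties
      int nl = k + 1, nr = n - nl;
      double ssl = cum_sq - cum_sumsq / nl;
      // right-side sum of squares from totals
      double rs_sumsq = 0.0;
      for (int j = 0; j < p; ++j) {
        double r = tot[j] - cum[j];
        rs_sumsq += r * r;
      }
      double ssr = (tot_sq - cum_sq) - rs_sumsq / nr;
      if (ssl < 0) ssl = 0;
      if (ssr < 0) ssr = 0;
      double gain = nd.ss - ssl - ssr;
      if (gain > gain_tol && gain > best.gain) {
        best.found = true; best.var = v;
        best.threshold = (xa + xb) / 2.0;
        best.gain = gain; best.ss_left = ssl; best.ss_right = ssr;
      }
      (void)sqnorm;
    }
  }
  return best;
}

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix Y, NumericMatrix X, int min_split,
                   int max_leaves) {
  int n = Y.nrow();
  if (X.nrow() != n) stop("response and constraints are misaligned");
  std::vector<Node> nodes;
  Node root;
  root.members.resize(n);
  for (int i = 0; i < n; ++i) root.members[i] = i;
  node_stats(Y, root.members, root.centroid, root.ss);
  root.left = root.right = -1; root.split_var = -1; root.threshold = NA_REAL;
  double gain_tol = 1e-12 * std::max(root.ss, 1.0);
  root.best = best_split(Y, X, root, min_split, gain_tol);
  nodes.push_back(root);

  int n_leaves = 1;
  while (n_leaves < max_leaves) {
    // pick the leaf with the largest achievable gain (ties: earliest created)
    int pick = -1; double bg = 0.0;
    for (size_t t = 0; t < nodes.size(); ++t) {
      if (nodes[t].left != -1 || !nodes[t].best.found) continue;
      if (nodes[t].best.gain > bg) { bg = nodes[t].best.gain; pick = (int)t; }
    }
    if (pick < 0) break;
    Node& par = nodes[pick];
    SplitResult sp = par.best;
    Node L, R;
    for (int k : par.members) {
      if (X(k, sp.var) < sp.threshold) L.members.push_back(k);
      else R.members.push_back(k);
    }
    node_stats(Y, L.members, L.centroid, L.ss);
    node_stats(Y, R.members, R.centroid, R.ss);
    L.left = L.right = R.left = R.right = -1;
    L.split_var = R.split_var = -1; L.threshold = R.threshold = NA_REAL;
    L.best = best_split(Y, X, L, min_split, gain_tol);
    R.best = best_split(Y, X, R, min_split, gain_tol);
    int li = (int)nodes.size(), ri = li + 1;
    nodes.push_back(L); nodes.push_back(R);
    nodes[pick].left = li; nodes[pick].right = ri;
    nodes[pick].split_var = sp.var; nodes[pick].threshold = sp.threshold;
    nodes[pick].best.found = false;
    ++n_leaves;
  }

  int m = (int)nodes.size(), p = Y.ncol();
  IntegerVector left(m), right(m), split_var(m), nsize(m);
  NumericVector threshold(m), ss(m);
  NumericMatrix centroids(m, p);
  IntegerVector leaf_of_site(n);
  List members(m);
  for (int t = 0; t < m; ++t) {
    left[t] = nodes[t].left + 1;            // 1-based, 0 = none
    right[t] = nodes[t].right + 1;
    split_var[t] = nodes[t].split_var + 1;  // 1-based, 0 = leaf
    threshold[t] = nodes[t].threshold;
    nsize[t] = (int)nodes[t].members.size();
    ss[t] = nodes[t].ss;
    for (int j = 0; j < p; ++j) centroids(t, j) = nodes[t].centroid[j];
    IntegerVector mem(nodes[t].members.size());
    for (size_t k = 0; k < nodes[t].members.size(); ++k)
      mem[k] = nodes[t].members[k] + 1;
    members[t] = mem;
    if (nodes[t].left == -1)
      for (int i : nodes[t].members) leaf_of_site[i] = t + 1;
  }
  return List::create(_["left"] = left, _["right"] = right,
                      _["split_var"] = split_var, _["threshold"] = threshold,
                      _["n"] = nsize, _["ss"] = ss,
                      _["centroids"] = centroids, _["members"] = members,
                      _["leaf_of_site"] = leaf_of_site);
}

// Weakest-link cost-complexity pruning. For internal node t with branch T_t,
// g(t) = (ss(t) - S(T_t)) / (leaves(T_t) - 1); the node(s) with minimal g are
// collapsed simultaneously and the process repeats until only the root
// remains. Returns, per node, the complexity at which it stops being internal
// (Inf for full-tree leaves) and the sequence (alpha, leaf count, relative
// resubstitution error).
// [[Rcpp::export]]
List prune_tree_cpp(IntegerVector left, IntegerVector right,
                    NumericVector ss) {
  int m = left.size();
  std::vector<int> L(m), R(m);
  for (int t = 0; t < m; ++t) { L[t] = left[t] - 1; R[t] = right[t] - 1; }
  std::vector<bool> internal(m);
  for (int t = 0; t < m; ++t) internal[t] = (L[t] >= 0);

  std::vector<double> S(m);      // sum of current-leaf ss within branch
  std::vector<int> nl(m);        // current leaf count within branch
  // children always appear after parents in creation order, so a reverse
  // sweep is a valid bottom-up pass
  for (int t = m - 1; t >= 0; --t) {
    if (!internal[t]) { S[t] = ss[t]; nl[t] = 1; }
    else { S[t] = S[L[t]] + S[R[t]]; nl[t] = nl[L[t]] + nl[R[t]]; }
  }
  double root_ss = ss[0];
  std::vector<double> prune_alpha(m, R_PosInf);

  std::vector<double> alphas; std::vector<int> sizes; std::vector<double> relerr;
  double rel0 = root_ss > 0 ? S[0] / root_ss : 1.0;
  alphas.push_back(0.0); sizes.push_back(nl[0]); relerr.push_back(rel0);

  while (internal[0]) {
    double amin = R_PosInf;
    for (int t = 0; t < m; ++t) {
      if (!internal[t]) continue;
      double g = (ss[t] - S[t]) / (nl[t] - 1);
      if (g < amin) amin = g;
    }
    double tol = 1e-10 * std::max(1.0, std::abs(amin));
    // collapse every node attaining the minimum
    for (int t = 0; t < m; ++t) {
      if (!internal[t]) continue;
      double g = (ss[t] - S[t]) / (nl[t] - 1);
      if (g <= amin + tol) {
        prune_alpha[t] = amin;
        internal[t] = false;
      }
    }
    // internal descendants of a collapsed node leave the tree with it
    std::vector<bool> reach(m, false);
    reach[0] = true;
    for (int t = 0; t < m; ++t) {       // parents precede children
      if (reach[t] && internal[t]) { reach[L[t]] = true; reach[R[t]] = true; }
    }
    for (int t = 0; t < m; ++t) {
      if (internal[t] && !reach[t]) { internal[t] = false; prune_alpha[t] = amin; }
    }
    // recompute branch stats bottom-up over the new structure
    for (int t = m - 1; t >= 0; --t) {
      if (!internal[t]) { S[t] = ss[t]; nl[t] = 1; }
      else { S[t] = S[L[t]] + S[R[t]]; nl[t] = nl[L[t]] + nl[R[t]]; }
    }
    alphas.push_back(amin); sizes.push_back(nl[0]);
    relerr.push_back(root_ss > 0 ? S[0] / root_ss : 1.0);
  }
  return List::create(_["alpha"] = wrap(alphas), _["size"] = wrap(sizes),
                      _["rel_error"] = wrap(relerr),
                      _["prune_alpha"] = wrap(prune_alpha));
}
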