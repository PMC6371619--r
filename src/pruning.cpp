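// Felsenstein pruning inner loop: below-partials for every node over the
// site patterns, with per-pattern rescaling to avoid underflow.
#include <Rcpp.h>
using namespace Rcpp;

// parent: length 2n-1, 1-based parent ids (0 at the root).
// pent: 16 x (2n-1) matrix, column b = column-major 4x4 transition matrix of
// the branch above node b+1 (P[x,y] = P(parent x -> child y)).
// tipstates: ntip x S, 1-based states.
// [[Rcpp::export(name = ".prune_partials_cpp")]]
List prune_partials_cpp(int ntip, IntegerVector parent, NumericMatrix pent,
                        IntegerMatrix tipstates) {
  const int m = 2 * ntip - 1;
  const int S = tipstates.ncol();
  // children and iterative-DFS postorder from the parent vector
  std::vector<int> child(2 * m, -1);
  int root = -1;
  for (int i = 0; i < m; ++i) {
    const int p = parent[i] - 1;
    if (p < 0) { root = i; continue; }
    if (child[2 * p] < 0) child[2 * p] = i; else child[2 * p + 1] = i;
  }
  std::vector<int> post; post.reserve(m);
  std::vector<int> stack; stack.reserve(m);
  std::vector<char> seen(m, 0);
  stack.push_back(root);
  while (!stack.empty()) {
    const int node = stack.back();
    if (node < ntip || seen[node]) {
      post.push_back(node);
      stack.pop_back();
    } else {
      seen[node] = 1;
      stack.push_back(child[2 * node]);
      stack.push_back(child[2 * node + 1]);
    }
  }
  NumericMatrix part(4 * m, S);
  NumericVector logscale(S);
  for (int i = 0; i < ntip; ++i)
    for (int j = 0; j < S; ++j)
      part(4 * i + tipstates(i, j) - 1, j) = 1.0;
  for (size_t k = 0; k < post.size(); ++k) {
    const int node = post[k];
    if (node < ntip) continue;
    const int c1 = child[2 * node];
    const int c2 = child[2 * node + 1];
    const double* P1 = &pent(0, c1);
    const double* P2 = &pent(0, c2);
    for (int j = 0; j < S; ++j) {
      double a[4] = {0, 0, 0, 0}, b[4] = {0, 0, 0, 0};
      for (int y = 0; y < 4; ++y) {
        const double l1 = part(4 * c1 + y, j);
        const double l2 = part(4 * c2 + y, j);
        if (l1 != 0)
          for (int x = 0; x < 4; ++x) a[x] += P1[x + 4 * y] * l1;
        if (l2 != 0)
          for (int x = 0; x < 4; ++x) b[x] += P2[x + 4 * y] * l2;
      }
      double v[4], mx = 0;
      for (int x = 0; x < 4; ++x) {
        v[x] = a[x] * b[x];
        if (v[x] > mx) mx = v[x];
      }
      if (mx <= 0) mx = 1;  // impossible pattern; root sum handles the -Inf
      for (int x = 0; x < 4; ++x) part(4 * node + x, j) = v[x] / mx;
      logscale[j] += std::log(mx);
    }
  }
  return List::create(_["partials"] = part, _["log_scale"] = logscale);
}
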