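#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 3-d k-d tree over the reference cloud (median split, cycled axes).
// Ties in query distance are broken toward the lowest reference index,
// which requires visiting the far subtree when the splitting-plane
// distance equals the current best (<=, not <).
namespace {

struct Node {
  int pt;
  int left;
  int right;
  int axis;
};

class KDTree {
public:
  const double* X;  // column-major n x 3
  int n;
  std::vector<Node> nodes;
  std::vector<int> perm;
  int root;

  KDTree(const double* X_, int n_) : X(X_), n(n_) {
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    nodes.reserve(n);
    root = build(0, n, 0);
  }

  double coord(int i, int ax) const { return X[i + ax * (size_t)n]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    int id = (int)nodes.size();
    nodes.push_back(Node{perm[mid], -1, -1, ax});
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void search(int node, const double* q, double& bd2, int& bi) const {
    if (node < 0) return;
    const Node& nd = nodes[node];
    const int p = nd.pt;
    const double dx = coord(p, 0) - q[0];
    const double dy = coord(p, 1) - q[1];
    const double dz = coord(p, 2) - q[2];
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bd2 || (d2 == bd2 && p < bi)) {
      bd2 = d2;
      bi = p;
    }
    const double diff = q[nd.axis] - coord(p, nd.axis);
    const int near_child = diff < 0 ? nd.left : nd.right;
    const int far_child = diff < 0 ? nd.right : nd.left;
    search(near_child, q, bd2, bi);
    if (diff * diff <= bd2) search(far_child, q, bd2, bi);
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_search_cpp")]]
List nn_search_cpp(NumericMatrix reference, NumericMatrix queries) {
  const int n = reference.nrow();
  const int m = queries.nrow();
  if (n < 1) stop("reference cloud is empty");
  if (reference.ncol() != 3 || queries.ncol() != 3)
    stop("point matrices must have 3 columns");
  KDTree tree(REAL(reference), n);
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int j = 0; j < m; ++j) {
    double q[3] = {queries(j, 0), queries(j, 1), queries(j, 2)};
    double bd2 = R_PosInf;
    int bi = n;
    tree.search(tree.root, q, bd2, bi);
    idx[j] = bi + 1;  // 1-based for R
    dist[j] = std::sqrt(bd2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
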