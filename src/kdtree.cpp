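// Static 3D kd-tree for nearest-neighbour correspondence queries in ICP.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

class KDTree3 {
public:
  std::vector<double> pts;  // x,y,z interleaved
  std::vector<int> order;
  int n;

  explicit KDTree3(const NumericMatrix &P) : n(P.nrow()) {
    pts.resize(3 * n);
    order.resize(n);
    for (int i = 0; i < n; ++i) {
      pts[3 * i] = P(i, 0);
      pts[3 * i + 1] = P(i, 1);
      pts[3 * i + 2] = P(i, 2);
      order[i] = i;
    }
    build(0, n, 0);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int ax = depth % 3;
    std::nth_element(order.begin() + lo, order.begin() + mid, order.begin() + hi,
                     [&](int a, int b) { return pts[3 * a + ax] < pts[3 * b + ax]; });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double *q, int lo, int hi, int depth, int &best, double &bestd) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int i = order[mid];
    double dx = pts[3 * i] - q[0], dy = pts[3 * i + 1] - q[1], dz = pts[3 * i + 2] - q[2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bestd) { bestd = d; best = i; }
    int ax = depth % 3;
    double diff = q[ax] - pts[3 * i + ax];
    if (diff < 0) {
      query(q, lo, mid, depth + 1, best, bestd);
      if (diff * diff < bestd) query(q, mid + 1, hi, depth + 1, best, bestd);
    } else {
      query(q, mid + 1, hi, depth + 1, best, bestd);
      if (diff * diff < bestd) query(q, lo, mid, depth + 1, best, bestd);
    }
  }
};

// [[Rcpp::export]]
SEXP kd_build(NumericMatrix pts) {
  XPtr<KDTree3> ptr(new KDTree3(pts), true);
  return ptr;
}

// [[Rcpp::export]]
List kd_query(SEXP tree, NumericMatrix query) {
  XPtr<KDTree3> ptr(tree);
  int m = query.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int best = -1;
    double bestd = R_PosInf;
    ptr->query(q, 0, ptr->n, 0, best, bestd);
    idx[i] = best + 1;
    dist[i] = std::sqrt(bestd);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
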