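#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Simple 3-d kd-tree over the rows of an N x 3 matrix. Nodes are stored in a
// pool; each subtree owns a contiguous index range with the splitting point
// at its front. Ties in nearest-neighbour distance are broken toward the
// smallest row index so every query is deterministic.

namespace {

struct KdTree {
  const double *pts;  // column-major N x 3
  int n;
  std::vector<int> idx;

  double coord(int i, int a) const { return pts[a * (size_t)n + i]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int axis = depth % 3;
    int mid = lo + (hi - lo) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, axis), cb = coord(b, axis);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void init(const double *p, int n_) {
    pts = p;
    n = n_;
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }

  double dist2(int i, const double *q) const {
    double s = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = coord(i, a) - q[a];
      s += d * d;
    }
    return s;
  }

  // Single nearest neighbour; best initialised to bound^2 (or inf).
  void nearest(int lo, int hi, int depth, const double *q, double &best,
               int &best_i) const {
    if (hi <= lo) return;
    int axis = depth % 3;
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    double d2 = dist2(i, q);
    if (d2 < best || (d2 == best && best_i >= 0 && i < best_i)) {
      best = d2;
      best_i = i;
    }
    double diff = q[axis] - coord(i, axis);
    int nlo1 = lo, nhi1 = mid, nlo2 = mid + 1, nhi2 = hi;
    if (diff > 0) {
      std::swap(nlo1, nlo2);
      std::swap(nhi1, nhi2);
    }
    nearest(nlo1, nhi1, depth + 1, q, best, best_i);
    if (diff * diff <= best) nearest(nlo2, nhi2, depth + 1, q, best, best_i);
  }

  // k nearest neighbours via a max-heap of (dist2, index).
  typedef std::pair<double, int> HeapItem;
  void knn(int lo, int hi, int depth, const double *q, int k,
           std::priority_queue<HeapItem> &heap) const {
    if (hi <= lo) return;
    int axis = depth % 3;
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    double d2 = dist2(i, q);
    if ((int)heap.size() < k) {
      heap.push(HeapItem(d2, i));
    } else if (d2 < heap.top().first ||
               (d2 == heap.top().first && i < heap.top().second)) {
      heap.pop();
      heap.push(HeapItem(d2, i));
    }
    double diff = q[axis] - coord(i, axis);
    int nlo1 = lo, nhi1 = mid, nlo2 = mid + 1, nhi2 = hi;
    if (diff > 0) {
      std::swap(nlo1, nlo2);
      std::swap(nhi1, nhi2);
    }
    knn(nlo1, nhi1, depth + 1, q, k, heap);
    if ((int)heap.size() < k || diff * diff <= heap.top().first)
      knn(nlo2, nhi2, depth + 1, q, k, heap);
  }
};

}  // namespace

// Nearest neighbour in `target` for each row of `query`.
// Returns 1-based indices and distances; index 0 where no point lies within
// `max_dist` (max_dist <= 0 means unbounded).
// [[Rcpp::export(name = ".cpp_nearest")]]
List cpp_nearest(NumericMatrix query, NumericMatrix target, double max_dist) {
  int nq = query.nrow(), nt = target.nrow();
  KdTree tree;
  tree.init(&target(0, 0), nt);
  IntegerVector out_idx(nq);
  NumericVector out_d(nq);
  double bound2 = (max_dist > 0) ? max_dist * max_dist : R_PosInf;
  for (int i = 0; i < nq; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double best = bound2 * (1.0 + 1e-12) + 1e-300;
    if (!R_FINITE(bound2)) best = R_PosInf;
    int best_i = -1;
    tree.nearest(0, nt, 0, q, best, best_i);
    if (best_i >= 0 && best <= bound2) {
      out_idx[i] = best_i + 1;
      out_d[i] = std::sqrt(best);
    } else {
      out_idx[i] = 0;
      out_d[i] = NA_REAL;
    }
  }
  return List::create(_["idx"] = out_idx, _["dist"] = out_d);
}

// k nearest neighbours of each row of `query` among rows of `target`.
// Returns an nq x k matrix of 1-based indices, each row sorted by distance.
// [[Rcpp::export(name = ".cpp_knn")]]
IntegerMatrix cpp_knn(NumericMatrix query, NumericMatrix target, int k) {
  int nq = query.nrow(), nt = target.nrow();
  if (k > nt) stop("k exceeds number of target points");
  KdTree tree;
  tree.init(&target(0, 0), nt);
  IntegerMatrix out(nq, k);
  for (int i = 0; i < nq; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    std::priority_queue<KdTree::HeapItem> heap;
    tree.knn(0, nt, 0, q, k, heap);
    std::vector<KdTree::HeapItem> items;
    while (!heap.empty()) {
      items.push_back(heap.top());
      heap.pop();
    }
    std::reverse(items.begin(), items.end());
    for (int j = 0; j < k; ++j) out(i, j) = items[j].second + 1;
  }
  return out;
}

// 8-connected component labelling of a binary matrix (column-major).
// Labels are assigned in column-major scan order starting at 1, so the
// component containing the scan-order-first pixel always has label 1.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// CRC-32 (ISO 3309 / PNG) of a raw vector.
// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
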