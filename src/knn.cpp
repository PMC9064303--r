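// Max-norm (Chebyshev) k-nearest-neighbour search on a kd-tree.
// Used by the interspike-interval history divergence estimators, where
// reference sets can reach ~50 * N_X points and brute force is infeasible.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int left = -1, right = -1;  // children; -1 when leaf
  int start = 0, end = 0;     // index range into perm
  int axis = 0;
  double split = 0.0;
};

class KDTree {
 public:
  int n = 0, d = 0;
  std::vector<double> pts;  // row-major n x d
  std::vector<int> perm;    // point indices, partitioned by the tree
  std::vector<Node> nodes;
  std::vector<double> box_lo, box_hi;  // per-node bounding boxes (node*d)
  static const int LEAF = 16;

  void build(const NumericMatrix& X) {
    n = X.nrow();
    d = X.ncol();
    pts.resize((size_t)n * d);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < d; ++j) pts[(size_t)i * d + j] = X(i, j);
    perm.resize(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    nodes.reserve(2 * n / LEAF + 8);
    build_rec(0, n);
  }

  int build_rec(int start, int end) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    box_lo.resize(box_lo.size() + d, R_PosInf);
    box_hi.resize(box_hi.size() + d, R_NegInf);
    double* blo = &box_lo[(size_t)id * d];
    double* bhi = &box_hi[(size_t)id * d];
    for (int t = start; t < end; ++t) {
      const double* x = &pts[(size_t)perm[t] * d];
      for (int j = 0; j < d; ++j) {
        if (x[j] < blo[j]) blo[j] = x[j];
        if (x[j] > bhi[j]) bhi[j] = x[j];
      }
    }
    Node nd;
    nd.start = start;
    nd.end = end;
    if (end - start <= LEAF) {
      nodes[id] = nd;
      return id;
    }
    // split on the axis of widest spread within this node
    int axis = 0;
    double best_spread = -1.0;
    for (int j = 0; j < d; ++j) {
      if (bhi[j] - blo[j] > best_spread) {
        best_spread = bhi[j] - blo[j];
        axis = j;
      }
    }
    nd.axis = axis;
    int mid = (start + end) / 2;
    std::nth_element(perm.begin() + start, perm.begin() + mid,
                     perm.begin() + end, [&](int a, int b) {
                       return pts[(size_t)a * d + axis] <
                              pts[(size_t)b * d + axis];
                     });
    nd.split = pts[(size_t)perm[mid] * d + axis];
    nodes[id] = nd;  // reserve slot before recursing
    int L = build_rec(start, mid);
    int R = build_rec(mid, end);
    nodes[id].left = L;
    nodes[id].right = R;
    return id;
  }

  // k best (distance, index) pairs maintained as a max-heap
  struct Heap {
    std::vector<std::pair<double, int>> h;
    int k;
    explicit Heap(int k_) : k(k_) { h.reserve(k_ + 1); }
    double worst() const {
      return (int)h.size() < k ? R_PosInf : h.front().first;
    }
    void offer(double dist, int idx) {
      if ((int)h.size() < k) {
        h.emplace_back(dist, idx);
        std::push_heap(h.begin(), h.end());
      } else if (dist < h.front().first) {
        std::pop_heap(h.begin(), h.end());
        h.back() = std::make_pair(dist, idx);
        std::push_heap(h.begin(), h.end());
      }
    }
  };

  void search(const double* q, int skip, Heap& heap, int node_id) const {
    const Node& nd = nodes[node_id];
    if (nd.left < 0) {
      for (int t = nd.start; t < nd.end; ++t) {
        int p = perm[t];
        if (p == skip) continue;
        const double* x = &pts[(size_t)p * d];
        double dist = 0.0, w = heap.worst();
        for (int j = 0; j < d; ++j) {
          double v = std::fabs(q[j] - x[j]);
          if (v > dist) {
            dist = v;
            if (dist >= w) break;  // max-norm: any axis exceeding bound kills
          }
        }
        if (dist < w) heap.offer(dist, p);
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    search(q, skip, heap, near);
    if (std::fabs(diff) < heap.worst()) search(q, skip, heap, far);
  }

  // kth-NN distance for each query row; self = TRUE means Q is the indexed
  // point set itself, so query i skips reference point i.
  NumericVector kth_dist(const NumericMatrix& Q, int k, bool self) const {
    int nq = Q.nrow();
    if (Q.ncol() != d) stop("query dimension does not match tree dimension");
    int avail = self ? n - 1 : n;
    if (k > avail) stop("k exceeds the number of available neighbours");
    NumericVector out(nq);
    std::vector<double> q(d);
    for (int i = 0; i < nq; ++i) {
      for (int j = 0; j < d; ++j) q[j] = Q(i, j);
      Heap heap(k);
      search(q.data(), self ? i : -1, heap, 0);
      out[i] = heap.h.front().first;
    }
    return out;
  }

  // count reference points with max-norm distance <= r from each query row;
  // self = TRUE means Q is the indexed point set itself, whose own point
  // (distance 0) is excluded from the count
  IntegerVector count_within(const NumericMatrix& Q, const NumericVector& r,
                             bool self) const {
    int nq = Q.nrow();
    if (Q.ncol() != d) stop("query dimension does not match tree dimension");
    if (r.size() != nq) stop("need one radius per query row");
    IntegerVector out(nq);
    std::vector<double> q(d);
    for (int i = 0; i < nq; ++i) {
      for (int j = 0; j < d; ++j) q[j] = Q(i, j);
      out[i] = count_rec(q.data(), r[i], 0) - (self ? 1 : 0);
    }
    return out;
  }

  int count_rec(const double* q, double r, int node_id) const {
    const Node& nd = nodes[node_id];
    const double* blo = &box_lo[(size_t)node_id * d];
    const double* bhi = &box_hi[(size_t)node_id * d];
    bool contained = true;
    for (int j = 0; j < d; ++j) {
      if (blo[j] > q[j] + r || bhi[j] < q[j] - r) return 0;  // disjoint
      if (q[j] - r > blo[j] || bhi[j] > q[j] + r) contained = false;
    }
    if (contained) return nd.end - nd.start;  // whole subtree inside ball
    if (nd.left < 0) {
      int cnt = 0;
      for (int t = nd.start; t < nd.end; ++t) {
        const double* x = &pts[(size_t)perm[t] * d];
        bool in = true;
        for (int j = 0; j < d; ++j) {
          if (std::fabs(q[j] - x[j]) > r) {
            in = false;
            break;
          }
        }
        if (in) ++cnt;
      }
      return cnt;
    }
    return count_rec(q, r, nd.left) + count_rec(q, r, nd.right);
  }

  // Per-call source-part bounding boxes over the same tree topology, with
  // src rows re-ordered to perm order for sequential leaf scans.
  void source_boxes(const double* src_perm, int ds, int node_id,
                    std::vector<double>& slo, std::vector<double>& shi) const {
    const Node& nd = nodes[node_id];
    double* lo = &slo[(size_t)node_id * ds];
    double* hi = &shi[(size_t)node_id * ds];
    if (nd.left < 0) {
      for (int j = 0; j < ds; ++j) {
        lo[j] = R_PosInf;
        hi[j] = R_NegInf;
      }
      for (int t = nd.start; t < nd.end; ++t) {
        const double* s = &src_perm[(size_t)t * ds];
        for (int j = 0; j < ds; ++j) {
          if (s[j] < lo[j]) lo[j] = s[j];
          if (s[j] > hi[j]) hi[j] = s[j];
        }
      }
      return;
    }
    source_boxes(src_perm, ds, nd.left, slo, shi);
    source_boxes(src_perm, ds, nd.right, slo, shi);
    const double* llo = &slo[(size_t)nd.left * ds];
    const double* lhi = &shi[(size_t)nd.left * ds];
    const double* rlo = &slo[(size_t)nd.right * ds];
    const double* rhi = &shi[(size_t)nd.right * ds];
    for (int j = 0; j < ds; ++j) {
      lo[j] = std::min(llo[j], rlo[j]);
      hi[j] = std::max(lhi[j], rhi[j]);
    }
  }

  // Fused count for the TE estimator: the tree indexes the target-part
  // embeddings of the random sample; src_perm holds the matching
  // source-part rows in perm order. For each query (qt, qs, radius r)
  // returns both the count of random points within r in target-part space
  // (n_tr) and the count of those additionally within r in source-part
  // space (n_jr).
  void count_joint(const double* qt, const double* qs, double r, int ds,
                   const double* src_perm, const std::vector<double>& slo,
                   const std::vector<double>& shi, int node_id, int* n_tr,
                   int* n_jr) const {
    const Node& nd = nodes[node_id];
    const double* blo = &box_lo[(size_t)node_id * d];
    const double* bhi = &box_hi[(size_t)node_id * d];
    bool t_contained = true;
    for (int j = 0; j < d; ++j) {
      if (blo[j] > qt[j] + r || bhi[j] < qt[j] - r) return;  // disjoint
      if (qt[j] - r > blo[j] || bhi[j] > qt[j] + r) t_contained = false;
    }
    const double* clo = &slo[(size_t)node_id * ds];
    const double* chi = &shi[(size_t)node_id * ds];
    bool s_contained = true, s_disjoint = false;
    for (int j = 0; j < ds; ++j) {
      if (clo[j] > qs[j] + r || chi[j] < qs[j] - r) {
        s_disjoint = true;
        break;
      }
      if (qs[j] - r > clo[j] || chi[j] > qs[j] + r) s_contained = false;
    }
    if (t_contained) {
      *n_tr += nd.end - nd.start;
      if (s_disjoint) return;
      if (s_contained) {
        *n_jr += nd.end - nd.start;
        return;
      }
      // target side fully inside: only the source test remains per point
      for (int t = nd.start; t < nd.end; ++t) {
        const double* s = &src_perm[(size_t)t * ds];
        bool in_s = true;
        for (int j = 0; j < ds; ++j) {
          if (std::fabs(qs[j] - s[j]) > r) {
            in_s = false;
            break;
          }
        }
        if (in_s) ++*n_jr;
      }
      return;
    }
    if (nd.left < 0) {
      for (int t = nd.start; t < nd.end; ++t) {
        const double* x = &pts[(size_t)perm[t] * d];
        bool in = true;
        for (int j = 0; j < d; ++j) {
          if (std::fabs(qt[j] - x[j]) > r) {
            in = false;
            break;
          }
        }
        if (!in) continue;
        ++*n_tr;
        if (s_disjoint) continue;
        const double* s = &src_perm[(size_t)t * ds];
        bool in_s = true;
        for (int j = 0; j < ds; ++j) {
          if (std::fabs(qs[j] - s[j]) > r) {
            in_s = false;
            break;
          }
        }
        if (in_s) ++*n_jr;
      }
      return;
    }
    count_joint(qt, qs, r, ds, src_perm, slo, shi, nd.left, n_tr, n_jr);
    count_joint(qt, qs, r, ds, src_perm, slo, shi, nd.right, n_tr, n_jr);
  }

  IntegerMatrix knn_idx(const NumericMatrix& Q, int k, bool self) const {
    int nq = Q.nrow();
    if (Q.ncol() != d) stop("query dimension does not match tree dimension");
    int avail = self ? n - 1 : n;
    if (k > avail) stop("k exceeds the number of available neighbours");
    IntegerMatrix out(nq, k);
    std::vector<double> q(d);
    for (int i = 0; i < nq; ++i) {
      for (int j = 0; j < d; ++j) q[j] = Q(i, j);
      Heap heap(k);
      search(q.data(), self ? i : -1, heap, 0);
      std::sort(heap.h.begin(), heap.h.end());
      for (int m = 0; m < k; ++m) out(i, m) = heap.h[m].second + 1;  // 1-based
    }
    return out;
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP cpp_kdtree_build(NumericMatrix X) {
  XPtr<KDTree> ptr(new KDTree(), true);
  ptr->build(X);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cpp_kdtree_kth_dist(SEXP tree, NumericMatrix Q, int k,
                                  bool self) {
  XPtr<KDTree> ptr(tree);
  return ptr->kth_dist(Q, k, self);
}

// [[Rcpp::export]]
IntegerMatrix cpp_kdtree_knn_idx(SEXP tree, NumericMatrix Q, int k,
                                 bool self) {
  XPtr<KDTree> ptr(tree);
  return ptr->knn_idx(Q, k, self);
}

// [[Rcpp::export]]
IntegerVector cpp_kdtree_count_within(SEXP tree, NumericMatrix Q,
                                      NumericVector r, bool self) {
  XPtr<KDTree> ptr(tree);
  return ptr->count_within(Q, r, self);
}

// [[Rcpp::export]]
IntegerMatrix cpp_kdtree_count_joint(SEXP tree, NumericMatrix Qt,
                                     NumericMatrix Qs, NumericMatrix Su,
                                     NumericVector r) {
  XPtr<KDTree> ptr(tree);
  int nq = Qt.nrow();
  int ds = Qs.ncol();
  if (Qt.ncol() != ptr->d) stop("query dimension does not match tree");
  if (Qs.nrow() != nq || r.size() != nq) stop("query sizes must agree");
  if (Su.nrow() != ptr->n || Su.ncol() != ds) {
    stop("source matrix must align with the indexed random sample");
  }
  // source rows re-ordered to tree (perm) order for sequential leaf scans
  std::vector<double> src_perm((size_t)Su.nrow() * ds);
  for (int t = 0; t < Su.nrow(); ++t) {
    int p = ptr->perm[t];
    for (int j = 0; j < ds; ++j) src_perm[(size_t)t * ds + j] = Su(p, j);
  }
  std::vector<double> slo((size_t)ptr->nodes.size() * ds);
  std::vector<double> shi((size_t)ptr->nodes.size() * ds);
  ptr->source_boxes(src_perm.data(), ds, 0, slo, shi);
  IntegerMatrix out(nq, 2);
  std::vector<double> qt(ptr->d), qs(ds);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < ptr->d; ++j) qt[j] = Qt(i, j);
    for (int j = 0; j < ds; ++j) qs[j] = Qs(i, j);
    int n_tr = 0, n_jr = 0;
    ptr->count_joint(qt.data(), qs.data(), r[i], ds, src_perm.data(), slo,
                     shi, 0, &n_tr, &n_jr);
    out(i, 0) = n_tr;
    out(i, 1) = n_jr;
  }
  return out;
}

// One-shot convenience: kth-NN max-norm distance of each row of Q within R.
// [[Rcpp::export]]
NumericVector cpp_kth_nn_dist(NumericMatrix Q, NumericMatrix R, int k,
                              bool self) {
  KDTree tree;
  tree.build(R);
  return tree.kth_dist(Q, k, self);
}
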