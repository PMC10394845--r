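// Low-level geometry kernels shared by the preprocessing, clustering,
// skeleton and network modules. All indices crossing the R boundary are
// 1-based; 0 marks "none"/padding.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static inline double sqdist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Column-major accessor for an N x 3 matrix stored in a NumericMatrix.
struct Pts {
  const double* x;
  const double* y;
  const double* z;
  int n;
  explicit Pts(const NumericMatrix& m)
    : x(&m(0, 0)), y(&m(0, 1)), z(&m(0, 2)), n(m.nrow()) {}
  inline void get(int i, double* out) const {
    out[0] = x[i]; out[1] = y[i]; out[2] = z[i];
  }
  inline double sq(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    return dx * dx + dy * dy + dz * dz;
  }
  inline double sqto(int i, const double* p) const {
    double dx = x[i] - p[0], dy = y[i] - p[1], dz = z[i] - p[2];
    return dx * dx + dy * dy + dz * dz;
  }
};

// Greedy maximin (farthest point) sampling. Ties broken by lowest index.
// [[Rcpp::export(name = ".fps_cpp")]]
IntegerVector fps_cpp(NumericMatrix pts, int n, int start) {
  Pts P(pts);
  const int N = P.n;
  if (n < 1 || n > N) stop("target_n out of range");
  if (start < 1 || start > N) stop("start_index out of range");
  std::vector<double> mind(N, std::numeric_limits<double>::infinity());
  IntegerVector out(n);
  int cur = start - 1;
  out[0] = cur + 1;
  for (int s = 1; s < n; ++s) {
    double best = -1.0;
    int besti = -1;
    for (int i = 0; i < N; ++i) {
      double d = P.sq(i, cur);
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) { best = mind[i]; besti = i; } // strict >: lowest index wins ties
    }
    cur = besti;
    out[s] = cur + 1;
    mind[cur] = -1.0; // never reselect
  }
  return out;
}

// k nearest neighbors of each query among support points (self not excluded;
// callers that need self-exclusion pass k+1 or use knn_self_cpp).
// [[Rcpp::export(name = ".knn_query_cpp")]]
List knn_query_cpp(NumericMatrix query, NumericMatrix support, int k) {
  Pts Q(query), S(support);
  if (k < 1 || k > S.n) stop("k out of range");
  IntegerMatrix idx(Q.n, k);
  NumericMatrix dst(Q.n, k);
  std::vector<std::pair<double, int> > heap; // max-heap of k best
  for (int q = 0; q < Q.n; ++q) {
    double p[3]; Q.get(q, p);
    heap.clear();
    for (int i = 0; i < S.n; ++i) {
      double d = S.sqto(i, p);
      if ((int)heap.size() < k) {
        heap.push_back(std::make_pair(d, i));
        std::push_heap(heap.begin(), heap.end());
      } else if (d < heap.front().first) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = std::make_pair(d, i);
        std::push_heap(heap.begin(), heap.end());
      }
    }
    std::sort(heap.begin(), heap.end()); // ascending distance, then index
    for (int j = 0; j < k; ++j) {
      idx(q, j) = heap[j].second + 1;
      dst(q, j) = std::sqrt(heap[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// k nearest neighbors of each point among the other points of one cloud.
// [[Rcpp::export(name = ".knn_self_cpp")]]
List knn_self_cpp(NumericMatrix pts, int k) {
  Pts P(pts);
  if (k < 1 || k > P.n - 1) stop("k out of range");
  IntegerMatrix idx(P.n, k);
  NumericMatrix dst(P.n, k);
  std::vector<std::pair<double, int> > heap;
  for (int q = 0; q < P.n; ++q) {
    heap.clear();
    for (int i = 0; i < P.n; ++i) {
      if (i == q) continue;
      double d = P.sq(i, q);
      if ((int)heap.size() < k) {
        heap.push_back(std::make_pair(d, i));
        std::push_heap(heap.begin(), heap.end());
      } else if (d < heap.front().first) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = std::make_pair(d, i);
        std::push_heap(heap.begin(), heap.end());
      }
    }
    std::sort(heap.begin(), heap.end());
    for (int j = 0; j < k; ++j) {
      idx(q, j) = heap[j].second + 1;
      dst(q, j) = std::sqrt(heap[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// All neighbors within eps (inclusive, self included), ascending index.
// [[Rcpp::export(name = ".radius_neighbors_cpp")]]
List radius_neighbors_cpp(NumericMatrix pts, double eps) {
  Pts P(pts);
  double e2 = eps * eps;
  List out(P.n);
  std::vector<int> buf;
  for (int q = 0; q < P.n; ++q) {
    buf.clear();
    for (int i = 0; i < P.n; ++i)
      if (P.sq(i, q) <= e2) buf.push_back(i + 1);
    out[q] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}

// Up to nsample support indices within `radius` of each centroid, ascending
// index, padded by repeating the first found index; a centroid whose ball is
// empty is padded with its own support index (centroid_idx).
// [[Rcpp::export(name = ".ball_query_cpp")]]
IntegerMatrix ball_query_cpp(NumericMatrix support, NumericMatrix centroids,
                             IntegerVector centroid_idx, double radius,
                             int nsample) {
  Pts S(support), C(centroids);
  IntegerMatrix out(C.n, nsample);
  const bool inf = !R_finite(radius);
  const double r2 = radius * radius;
  for (int c = 0; c < C.n; ++c) {
    double p[3]; C.get(c, p);
    int found = 0;
    if (inf) {
      for (int i = 0; i < S.n && found < nsample; ++i) out(c, found++) = i + 1;
    } else {
      for (int i = 0; i < S.n && found < nsample; ++i)
        if (S.sqto(i, p) <= r2) out(c, found++) = i + 1;
    }
    int pad = (found > 0) ? out(c, 0) : centroid_idx[c];
    for (int j = found; j < nsample; ++j) out(c, j) = pad;
  }
  return out;
}

// Per-group column maxima with argmax rows, for contiguous groups of S rows.
// X is (G*S) x C; returns max (G x C) and 1-based row-of-X argmax (G x C).
// [[Rcpp::export(name = ".group_max_cpp")]]
List group_max_cpp(NumericMatrix X, int S) {
  const int rows = X.nrow(), C = X.ncol();
  if (rows % S != 0) stop("row count not divisible by group size");
  const int G = rows / S;
  NumericMatrix mx(G, C);
  IntegerMatrix am(G, C);
  for (int c = 0; c < C; ++c) {
    const double* col = &X(0, c);
    for (int g = 0; g < G; ++g) {
      const int base = g * S;
      double best = col[base];
      int bi = base;
      for (int s = 1; s < S; ++s) {
        double v = col[base + s];
        if (v > best) { best = v; bi = base + s; }
      }
      mx(g, c) = best;
      am(g, c) = bi + 1;
    }
  }
  return List::create(_["max"] = mx, _["argmax"] = am);
}

// Single-source shortest paths (Dijkstra) on the implicit radius graph:
// an edge joins i and j when d(i,j) <= max(radius[i], radius[j]), with
// weight d(i,j). Returns 1-based parents (0 for root/unreached) and
// distances (Inf when unreached).
// [[Rcpp::export(name = ".dijkstra_radius_cpp")]]
List dijkstra_radius_cpp(NumericMatrix pts, int root, NumericVector radius) {
  Pts P(pts);
  const int N = P.n;
  if (root < 1 || root > N) stop("root out of range");
  std::vector<double> dist(N, std::numeric_limits<double>::infinity());
  std::vector<int> parent(N, 0);
  std::vector<char> done(N, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[root - 1] = 0.0;
  pq.push(std::make_pair(0.0, root - 1));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    double ru = radius[u];
    for (int v = 0; v < N; ++v) {
      if (done[v] || v == u) continue;
      double r = std::max(ru, (double)radius[v]);
      double d2 = P.sq(u, v);
      if (d2 > r * r) continue;
      double nd = dist[u] + std::sqrt(d2);
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u + 1;
        pq.push(std::make_pair(nd, v));
      }
    }
  }
  return List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["dist"] = NumericVector(dist.begin(), dist.end()));
}

// Minimum distance from each point to a polyline (ordered vertices,
// distance to segments, not vertices).
// [[Rcpp::export(name = ".polyline_dist_cpp")]]
NumericVector polyline_dist_cpp(NumericMatrix pts, NumericMatrix poly) {
  Pts P(pts), L(poly);
  const int nseg = L.n - 1;
  NumericVector out(P.n);
  if (L.n == 1) {
    double a[3]; L.get(0, a);
    for (int i = 0; i < P.n; ++i) out[i] = std::sqrt(P.sqto(i, a));
    return out;
  }
  for (int i = 0; i < P.n; ++i) {
    double p[3]; P.get(i, p);
    double best = std::numeric_limits<double>::infinity();
    for (int s = 0; s < nseg; ++s) {
      double a[3], b[3];
      L.get(s, a); L.get(s + 1, b);
      double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
      double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
      double den = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
      double t = den > 0 ? (ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2]) / den : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Incremental 3-D convex hull volume (beneath-beyond). Degenerate inputs
// (fewer than 4 points, collinear or coplanar sets) return 0.

struct Face {
  int a, b, c;
  bool alive;
  double nx, ny, nz, off; // outward unit normal and plane offset (n.p = off)
};

static inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}

static inline double signed_vol(const double* a, const double* b,
                                const double* c, const double* d) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ac[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double ad[3] = { d[0] - a[0], d[1] - a[1], d[2] - a[2] };
  double cr[3];
  cross3(ab, ac, cr);
  return (cr[0] * ad[0] + cr[1] * ad[1] + cr[2] * ad[2]) / 6.0;
}

// outward-oriented face (relative to interior point O) with its unit plane
// equation n.p = off
static Face make_face(const std::vector<double>& P, const double* O,
                      int a, int b, int c) {
  Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
  double ab[3] = { P[3 * b] - P[3 * a], P[3 * b + 1] - P[3 * a + 1],
                   P[3 * b + 2] - P[3 * a + 2] };
  double ac[3] = { P[3 * c] - P[3 * a], P[3 * c + 1] - P[3 * a + 1],
                   P[3 * c + 2] - P[3 * a + 2] };
  double n[3];
  cross3(ab, ac, n);
  double len = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (len > 0) { n[0] /= len; n[1] /= len; n[2] /= len; }
  double off = n[0] * P[3 * a] + n[1] * P[3 * a + 1] + n[2] * P[3 * a + 2];
  if (n[0] * O[0] + n[1] * O[1] + n[2] * O[2] > off) {
    std::swap(f.b, f.c);
    n[0] = -n[0]; n[1] = -n[1]; n[2] = -n[2]; off = -off;
  }
  f.nx = n[0]; f.ny = n[1]; f.nz = n[2]; f.off = off;
  return f;
}

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix pts) {
  const int N = pts.nrow();
  if (N < 4) return 0.0;
  std::vector<double> P(3 * N);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      P[3 * i + d] = v;
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double scale = 0.0;
  for (int d = 0; d < 3; ++d) scale = std::max(scale, hi[d] - lo[d]);
  if (scale <= 0) return 0.0;
  const double eps = 1e-10 * scale * scale * scale; // volume-scale tolerance

  // Initial simplex: min-x point, its farthest point, then max-area,
  // then max-|volume|.
  int i0 = 0, i1 = 0;
  for (int i = 1; i < N; ++i)
    if (P[3 * i] < P[3 * i0]) i0 = i;
  double best = 0.0;
  for (int i = 0; i < N; ++i) {
    double dx = P[3 * i] - P[3 * i0], dy = P[3 * i + 1] - P[3 * i0 + 1],
           dz = P[3 * i + 2] - P[3 * i0 + 2];
    double d = dx * dx + dy * dy + dz * dz;
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= 0) return 0.0;
  int i2 = -1;
  best = 0.0;
  for (int i = 0; i < N; ++i) {
    double ab[3] = { P[3 * i1] - P[3 * i0], P[3 * i1 + 1] - P[3 * i0 + 1],
                     P[3 * i1 + 2] - P[3 * i0 + 2] };
    double ac[3] = { P[3 * i] - P[3 * i0], P[3 * i + 1] - P[3 * i0 + 1],
                     P[3 * i + 2] - P[3 * i0 + 2] };
    double cr[3];
    cross3(ab, ac, cr);
    double a2 = cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2];
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= 1e-24 * scale * scale * scale * scale) return 0.0;
  int i3 = -1;
  best = 0.0;
  for (int i = 0; i < N; ++i) {
    double v = std::fabs(signed_vol(&P[3 * i0], &P[3 * i1], &P[3 * i2], &P[3 * i]));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= eps) return 0.0;

  // interior reference point
  double O[3];
  for (int d = 0; d < 3; ++d)
    O[d] = (P[3 * i0 + d] + P[3 * i1 + d] + P[3 * i2 + d] + P[3 * i3 + d]) / 4.0;

  const double eps_dist = 1e-9 * scale; // point-plane visibility tolerance

  std::vector<Face> faces;
  faces.reserve(256);
  // build an outward-oriented face with its unit plane equation
#define MAKE_FACE(A, B, C) make_face(P, O, (A), (B), (C))
  int init[4][3] = { { i0, i1, i2 }, { i0, i1, i3 }, { i0, i2, i3 }, { i1, i2, i3 } };
  for (int f = 0; f < 4; ++f)
    faces.push_back(MAKE_FACE(init[f][0], init[f][1], init[f][2]));

  // farthest-first insertion keeps the face list small and well-conditioned
  std::vector<std::pair<double, int> > byd;
  byd.reserve(N);
  for (int i = 0; i < N; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    double dx = P[3 * i] - O[0], dy = P[3 * i + 1] - O[1],
           dz = P[3 * i + 2] - O[2];
    byd.push_back(std::make_pair(-(dx * dx + dy * dy + dz * dz), i));
  }
  std::sort(byd.begin(), byd.end());

  std::vector<int> visible;
  size_t n_dead = 0;
  for (size_t oi = 0; oi < byd.size(); ++oi) {
    int i = byd[oi].second;
    const double* p = &P[3 * i];
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (faces[f].nx * p[0] + faces[f].ny * p[1] + faces[f].nz * p[2] -
          faces[f].off > eps_dist)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon edges: directed edges of visible faces whose reverse is not
    // in the visible set
    std::vector<std::pair<int, int> > edges;
    for (size_t k = 0; k < visible.size(); ++k) {
      const Face& f = faces[visible[k]];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    for (size_t k = 0; k < visible.size(); ++k) faces[visible[k]].alive = false;
    n_dead += visible.size();
    for (size_t e = 0; e < edges.size(); ++e) {
      bool internal = false;
      for (size_t e2 = 0; e2 < edges.size(); ++e2)
        if (edges[e2].first == edges[e].second && edges[e2].second == edges[e].first) {
          internal = true;
          break;
        }
      if (internal) continue;
      faces.push_back(MAKE_FACE(edges[e].first, edges[e].second, i));
    }
    // compact the face list once dead entries dominate
    if (n_dead > 256 && n_dead > faces.size() / 2) {
      std::vector<Face> keep;
      keep.reserve(faces.size() - n_dead);
      for (size_t f = 0; f < faces.size(); ++f)
        if (faces[f].alive) keep.push_back(faces[f]);
      faces.swap(keep);
      n_dead = 0;
    }
  }
#undef MAKE_FACE

  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    vol += -signed_vol(&P[3 * faces[f].a], &P[3 * faces[f].b],
                       &P[3 * faces[f].c], O);
  }
  return vol < 0 ? 0.0 : vol;
}
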