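// Mesh-mesh minimum distance queries.
//
// cpp_brute_distance: exhaustive minimum over all triangle pairs (the oracle).
// cpp_mesh_distance:  AABB-tree accelerated, must agree with the oracle.
// cpp_group_distances: pairwise distances between two lists of meshes with
//                      each tree built once (used by configuration sweeps).
//
// All distances are surface distances: 0 when the surfaces intersect or
// touch; a solid strictly containing another (no surface crossing) reports
// the positive surface-to-surface distance.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct V3 {
  double x, y, z;
};

static inline V3 mk(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 operator-(const V3 &a, const V3 &b) { return mk(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator+(const V3 &a, const V3 &b) { return mk(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator*(const V3 &a, double s) { return mk(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return mk(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm2(const V3 &a) { return dot(a, a); }
static inline double clamp01(double t) { return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t); }

// Closest-point distance^2 between segments p1q1 and p2q2 (Ericson,
// Real-Time Collision Detection, 5.1.9).
static double segSegDist2(const V3 &p1, const V3 &q1, const V3 &p2, const V3 &q2) {
  const double EPS = 1e-14;
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s, t;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = clamp01(f / e); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0.0; s = clamp01(-c / a); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = (denom > EPS) ? clamp01((b * f - c * e) / denom) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = clamp01(-c / a); }
      else if (t > 1.0) { t = 1.0; s = clamp01((b - c) / a); }
    }
  }
  V3 c1 = p1 + d1 * s, c2 = p2 + d2 * t;
  return norm2(c1 - c2);
}

// Closest point on triangle abc to point p (Ericson 5.1.5); returns distance^2.
static double pointTriDist2(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return norm2(p - a);
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return norm2(p - b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return norm2(p - (a + ab * v));
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return norm2(p - c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return norm2(p - (a + ac * w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return norm2(p - (b + (c - b) * w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return norm2(p - (a + ab * v + ac * w));
}

// Does segment pq cross the interior of triangle abc? (Moller-Trumbore,
// inclusive of boundary within a small tolerance.)
static bool segIntersectsTri(const V3 &p, const V3 &q,
                             const V3 &a, const V3 &b, const V3 &c) {
  const double EPS = 1e-12;
  V3 dir = q - p;
  V3 e1 = b - a, e2 = c - a;
  V3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < EPS) return false; // parallel: handled by distance terms
  double inv = 1.0 / det;
  V3 s = p - a;
  double u = dot(s, h) * inv;
  if (u < -EPS || u > 1.0 + EPS) return false;
  V3 qv = cross(s, e1);
  double v = dot(dir, qv) * inv;
  if (v < -EPS || u + v > 1.0 + EPS) return false;
  double t = dot(e2, qv) * inv;
  return t >= -EPS && t <= 1.0 + EPS;
}

// Segment-triangle distance^2: 0 if the segment pierces the triangle,
// otherwise min over endpoint-triangle and segment-edge distances.
static double segTriDist2(const V3 &p, const V3 &q,
                          const V3 &a, const V3 &b, const V3 &c) {
  if (segIntersectsTri(p, q, a, b, c)) return 0.0;
  double d = pointTriDist2(p, a, b, c);
  d = std::min(d, pointTriDist2(q, a, b, c));
  d = std::min(d, segSegDist2(p, q, a, b));
  d = std::min(d, segSegDist2(p, q, b, c));
  d = std::min(d, segSegDist2(p, q, c, a));
  return d;
}

static double triTriDist2(const V3 *A, const V3 *B) {
  double d = std::numeric_limits<double>::infinity();
  for (int i = 0; i < 3; ++i) {
    d = std::min(d, segTriDist2(A[i], A[(i + 1) % 3], B[0], B[1], B[2]));
    if (d == 0.0) return 0.0;
    d = std::min(d, segTriDist2(B[i], B[(i + 1) % 3], A[0], A[1], A[2]));
    if (d == 0.0) return 0.0;
  }
  return d;
}

struct TriSoup {
  std::vector<V3> v;          // vertices
  std::vector<std::array<int, 3>> f; // 0-based triangles
  void fill(const NumericMatrix &V, const IntegerMatrix &F) {
    v.resize(V.nrow());
    for (int i = 0; i < V.nrow(); ++i) v[i] = mk(V(i, 0), V(i, 1), V(i, 2));
    f.resize(F.nrow());
    for (int i = 0; i < F.nrow(); ++i) {
      f[i] = { F(i, 0) - 1, F(i, 1) - 1, F(i, 2) - 1 };
      for (int k = 0; k < 3; ++k)
        if (f[i][k] < 0 || f[i][k] >= (int)v.size())
          stop("triangle index out of range");
    }
  }
  void tri(int i, V3 *out) const {
    out[0] = v[f[i][0]]; out[1] = v[f[i][1]]; out[2] = v[f[i][2]];
  }
};

// ----------------------------------------------------------------------------
// AABB tree
// ----------------------------------------------------------------------------

struct BVHNode {
  V3 lo, hi;
  int left, right;  // children, -1 for leaf
  int start, count; // leaf triangle range into 'order'
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
  const TriSoup *soup;

  void triBounds(int t, V3 &lo, V3 &hi) const {
    V3 T[3];
    soup->tri(t, T);
    lo = hi = T[0];
    for (int k = 1; k < 3; ++k) {
      lo.x = std::min(lo.x, T[k].x); lo.y = std::min(lo.y, T[k].y); lo.z = std::min(lo.z, T[k].z);
      hi.x = std::max(hi.x, T[k].x); hi.y = std::max(hi.y, T[k].y); hi.z = std::max(hi.z, T[k].z);
    }
  }

  int build(int start, int count, const std::vector<V3> &cent) {
    BVHNode nd;
    nd.start = start; nd.count = count; nd.left = nd.right = -1;
    triBounds(order[start], nd.lo, nd.hi);
    for (int i = 1; i < count; ++i) {
      V3 lo, hi;
      triBounds(order[start + i], lo, hi);
      nd.lo.x = std::min(nd.lo.x, lo.x); nd.lo.y = std::min(nd.lo.y, lo.y); nd.lo.z = std::min(nd.lo.z, lo.z);
      nd.hi.x = std::max(nd.hi.x, hi.x); nd.hi.y = std::max(nd.hi.y, hi.y); nd.hi.z = std::max(nd.hi.z, hi.z);
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) return id;
    V3 ext = nd.hi - nd.lo;
    int axis = 0;
    if (ext.y > ext.x) axis = 1;
    if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
    int mid = count / 2;
    std::nth_element(order.begin() + start, order.begin() + start + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       const V3 &ca = cent[a], &cb = cent[b];
                       return (axis == 0 ? ca.x < cb.x : axis == 1 ? ca.y < cb.y : ca.z < cb.z);
                     });
    int l = build(start, mid, cent);
    int r = build(start + mid, count - mid, cent);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void init(const TriSoup *s) {
    soup = s;
    int n = (int)s->f.size();
    if (n == 0) stop("empty mesh");
    order.resize(n);
    std::vector<V3> cent(n);
    for (int i = 0; i < n; ++i) {
      order[i] = i;
      V3 T[3];
      s->tri(i, T);
      cent[i] = (T[0] + T[1] + T[2]) * (1.0 / 3.0);
    }
    nodes.reserve(2 * n);
    build(0, n, cent);
  }
};

static inline double aabbDist2(const BVHNode &a, const BVHNode &b) {
  double d = 0.0, t;
  t = std::max(std::max(a.lo.x - b.hi.x, b.lo.x - a.hi.x), 0.0); d += t * t;
  t = std::max(std::max(a.lo.y - b.hi.y, b.lo.y - a.hi.y), 0.0); d += t * t;
  t = std::max(std::max(a.lo.z - b.hi.z, b.lo.z - a.hi.z), 0.0); d += t * t;
  return d;
}

static void queryBVH(const BVH &A, int na, const BVH &B, int nb, double &best2) {
  const BVHNode &x = A.nodes[na];
  const BVHNode &y = B.nodes[nb];
  if (aabbDist2(x, y) >= best2) return;
  bool xl = x.left < 0, yl = y.left < 0;
  if (xl && yl) {
    V3 TA[3], TB[3];
    for (int i = 0; i < x.count; ++i) {
      A.soup->tri(A.order[x.start + i], TA);
      for (int j = 0; j < y.count; ++j) {
        B.soup->tri(B.order[y.start + j], TB);
        double d = triTriDist2(TA, TB);
        if (d < best2) {
          best2 = d;
          if (best2 == 0.0) return;
        }
      }
    }
    return;
  }
  // descend the larger box first toward the closer child
  if (yl || (!xl && (norm2(x.hi - x.lo) > norm2(y.hi - y.lo)))) {
    double dl = aabbDist2(A.nodes[x.left], y);
    double dr = aabbDist2(A.nodes[x.right], y);
    if (dl < dr) {
      if (dl < best2) queryBVH(A, x.left, B, nb, best2);
      if (dr < best2) queryBVH(A, x.right, B, nb, best2);
    } else {
      if (dr < best2) queryBVH(A, x.right, B, nb, best2);
      if (dl < best2) queryBVH(A, x.left, B, nb, best2);
    }
  } else {
    double dl = aabbDist2(x, B.nodes[y.left]);
    double dr = aabbDist2(x, B.nodes[y.right]);
    if (dl < dr) {
      if (dl < best2) queryBVH(A, na, B, y.left, best2);
      if (dr < best2) queryBVH(A, na, B, y.right, best2);
    } else {
      if (dr < best2) queryBVH(A, na, B, y.right, best2);
      if (dl < best2) queryBVH(A, na, B, y.left, best2);
    }
  }
}

// [[Rcpp::export]]
double cpp_mesh_distance(NumericMatrix VA, IntegerMatrix FA,
                         NumericMatrix VB, IntegerMatrix FB) {
  TriSoup a, b;
  a.fill(VA, FA);
  b.fill(VB, FB);
  BVH ta, tb;
  ta.init(&a);
  tb.init(&b);
  double best2 = std::numeric_limits<double>::infinity();
  queryBVH(ta, 0, tb, 0, best2);
  return std::sqrt(best2);
}

// [[Rcpp::export]]
double cpp_brute_distance(NumericMatrix VA, IntegerMatrix FA,
                          NumericMatrix VB, IntegerMatrix FB) {
  TriSoup a, b;
  a.fill(VA, FA);
  b.fill(VB, FB);
  double best2 = std::numeric_limits<double>::infinity();
  V3 TA[3], TB[3];
  for (size_t i = 0; i < a.f.size(); ++i) {
    a.tri((int)i, TA);
    for (size_t j = 0; j < b.f.size(); ++j) {
      b.tri((int)j, TB);
      double d = triTriDist2(TA, TB);
      if (d < best2) {
        best2 = d;
        if (best2 == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best2);
}

// Gantry sweep: meshes in VA/FA are rotated about +Y through each angle
// (degrees) while VB/FB stay fixed; fixed trees are built once for the
// whole sweep. Returns an (na*nb) x n_angles matrix of pair distances,
// pair (i, j) in row i + na*j (column-major over the pair grid).
// [[Rcpp::export]]
NumericMatrix cpp_sweep_gantry(List VA, List FA, List VB, List FB,
                               NumericVector angles_deg, double cap_mm) {
  int na = VA.size(), nb = VB.size(), nt = angles_deg.size();
  std::vector<NumericMatrix> va(na);
  std::vector<TriSoup> sb(nb);
  std::vector<BVH> tb(nb);
  std::vector<IntegerMatrix> fa(na);
  for (int i = 0; i < na; ++i) {
    va[i] = as<NumericMatrix>(VA[i]);
    fa[i] = as<IntegerMatrix>(FA[i]);
  }
  for (int j = 0; j < nb; ++j) {
    sb[j].fill(as<NumericMatrix>(VB[j]), as<IntegerMatrix>(FB[j]));
    tb[j].init(&sb[j]);
  }
  NumericMatrix out(na * nb, nt);
  std::vector<TriSoup> sa(na);
  std::vector<BVH> ta(na);
  for (int t = 0; t < nt; ++t) {
    double th = angles_deg[t] * M_PI / 180.0;
    double c = std::cos(th), s = std::sin(th);
    for (int i = 0; i < na; ++i) {
      const NumericMatrix &V = va[i];
      int n = V.nrow();
      sa[i].v.resize(n);
      for (int k = 0; k < n; ++k) {
        double x = V(k, 0), y = V(k, 1), z = V(k, 2);
        sa[i].v[k] = mk(c * x + s * z, y, -s * x + c * z);
      }
      if (t == 0) {
        const IntegerMatrix &F = fa[i];
        sa[i].f.resize(F.nrow());
        for (int r = 0; r < F.nrow(); ++r)
          sa[i].f[r] = { F(r, 0) - 1, F(r, 1) - 1, F(r, 2) - 1 };
      }
      ta[i] = BVH();
      ta[i].init(&sa[i]);
    }
    double cap2 = R_FINITE(cap_mm) ? cap_mm * cap_mm
                                   : std::numeric_limits<double>::infinity();
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j) {
        double best2 = cap2;   // distances beyond the cap report the cap
        queryBVH(ta[i], 0, tb[j], 0, best2);
        out(i + na * j, t) = std::sqrt(best2);
      }
  }
  return out;
}

// Pairwise distances between two groups of meshes; every tree built once.
// [[Rcpp::export]]
NumericMatrix cpp_group_distances(List VA, List FA, List VB, List FB) {
  int na = VA.size(), nb = VB.size();
  std::vector<TriSoup> sa(na), sb(nb);
  std::vector<BVH> ta(na), tb(nb);
  for (int i = 0; i < na; ++i) {
    sa[i].fill(as<NumericMatrix>(VA[i]), as<IntegerMatrix>(FA[i]));
    ta[i].init(&sa[i]);
  }
  for (int j = 0; j < nb; ++j) {
    sb[j].fill(as<NumericMatrix>(VB[j]), as<IntegerMatrix>(FB[j]));
    tb[j].init(&sb[j]);
  }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double best2 = std::numeric_limits<double>::infinity();
      queryBVH(ta[i], 0, tb[j], 0, best2);
      out(i, j) = std::sqrt(best2);
    }
  return out;
}
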