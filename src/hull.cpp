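#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3-D convex hull used for pocket volumes. Grid-point inputs
// are massively degenerate (collinear triples, coplanar quadruples), so
// every point is perturbed by a small deterministic joggle before
// insertion, which puts the set in general position; orientation tests
// then use exact signs (the joggle-induced determinant magnitudes dwarf
// floating-point noise). The volume error introduced by the joggle is
// O(surface area x joggle), i.e. ~1e-4 relative, far below the tolerances
// pocket volumes are used at.

struct Face { int a, b, c; bool alive; };

static inline double det3(const double* p, const double* q, const double* r,
                          const double* s) {
  const double ax = q[0] - p[0], ay = q[1] - p[1], az = q[2] - p[2];
  const double bx = r[0] - p[0], by = r[1] - p[1], bz = r[2] - p[2];
  const double cx = s[0] - p[0], cy = s[1] - p[1], cz = s[2] - p[2];
  return ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
         az * (bx * cy - by * cx);
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], pts(i, d));
      hi[d] = std::max(hi[d], pts(i, d));
    }
  double scale = 0.0;
  for (int d = 0; d < 3; ++d) scale = std::max(scale, hi[d] - lo[d]);
  if (scale <= 0) return 0.0;

  // deterministic joggle via a fixed LCG (independent of R's RNG)
  std::vector<double> P(3 * (size_t)n);
  unsigned long long s = 88172645463325252ULL;
  const double jog = 1e-5 * scale;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      s = s * 6364136223846793005ULL + 1442695040888963407ULL;
      const double u = (double)(s >> 11) / 9007199254740992.0; // [0,1)
      P[3 * (size_t)i + d] = pts(i, d) + (2.0 * u - 1.0) * jog;
    }
  const double* pp = P.data();
#define PT(i) (pp + 3 * (size_t)(i))

  // initial tetrahedron from greedy extremes
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d2 = 0;
    for (int d = 0; d < 3; ++d) {
      const double t = PT(i)[d] - PT(i0)[d];
      d2 += t * t;
    }
    if (d2 > best) { best = d2; i1 = i; }
  }
  if (best <= 0) return 0.0;
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    const double ux = PT(i1)[0] - PT(i0)[0], uy = PT(i1)[1] - PT(i0)[1],
                 uz = PT(i1)[2] - PT(i0)[2];
    const double vx = PT(i)[0] - PT(i0)[0], vy = PT(i)[1] - PT(i0)[1],
                 vz = PT(i)[2] - PT(i0)[2];
    const double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
                 cz = ux * vy - uy * vx;
    const double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= 0) return 0.0;
  int i3 = -1; best = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    const double v = det3(PT(i0), PT(i1), PT(i2), PT(i));
    if (std::fabs(v) > best) { best = std::fabs(v); i3 = i; }
  }
  // an input that is coplanar before joggling: spanned volume is at the
  // joggle scale only -> report zero (degenerate)
  if (i3 < 0 || best <= 1e-4 * scale * scale * scale) return 0.0;

  double o[3]; // interior reference point, inside every intermediate hull
  for (int d = 0; d < 3; ++d)
    o[d] = (PT(i0)[d] + PT(i1)[d] + PT(i2)[d] + PT(i3)[d]) / 4.0;

  // Convention: faces stored with o on their negative side
  // (det3(a,b,c,o) < 0); p strictly outside a face iff det3(a,b,c,p) > 0.
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    if (det3(PT(a), PT(b), PT(c), o) > 0) std::swap(b, c);
    faces.push_back({a, b, c, true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (det3(PT(faces[f].a), PT(faces[f].b), PT(faces[f].c), PT(p)) > 0)
        vis.push_back((int)f);
    }
    if (vis.empty()) continue; // inside current hull
    // horizon = directed edges of visible faces whose reverse is absent
    std::map<std::pair<int, int>, int> edges;
    for (int f : vis) {
      const Face& F = faces[f];
      const int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (int t = 0; t < 3; ++t) edges[{e[t][0], e[t][1]}]++;
      faces[f].alive = false;
    }
    for (const auto& kv : edges) {
      const int a = kv.first.first, b = kv.first.second;
      if (edges.count({b, a})) continue; // interior edge of the visible patch
      add_face(a, b, p);
    }
  }

  double vol6 = 0.0;
  for (const Face& F : faces) {
    if (!F.alive) continue;
    vol6 += det3(PT(F.a), PT(F.b), PT(F.c), o);
  }
#undef PT
  return std::fabs(vol6) / 6.0;
}
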