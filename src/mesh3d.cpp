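// Iso-surface extraction by marching tetrahedra (each grid cell split into
// six tetrahedra sharing the main diagonal; surface vertices by linear
// interpolation) and an incremental 3D quickhull for convex-hull area,
// volume and point-in-hull tests. Coordinates are world mm: index * spacing.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// cube-corner offsets, order: (i,j,k)
static const int CORN[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
// six tetrahedra around the 0-6 diagonal
static const int TETS[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                               {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

// [[Rcpp::export]]
Rcpp::List cpp_marching_tets(const arma::cube& f, const double iso,
                             const arma::vec& spacing) {
  const int n1 = f.n_rows, n2 = f.n_cols, n3 = f.n_slices;
  std::vector<double> tri;  // 9 doubles per triangle
  double area = 0.0;
  double pos[8][3], cv[8];
  for (int k = 0; k < n3 - 1; ++k)
    for (int j = 0; j < n2 - 1; ++j)
      for (int i = 0; i < n1 - 1; ++i) {
        double lo = 1e300, hi = -1e300;
        for (int c = 0; c < 8; ++c) {
          cv[c] = f(i + CORN[c][0], j + CORN[c][1], k + CORN[c][2]);
          if (cv[c] < lo) lo = cv[c];
          if (cv[c] > hi) hi = cv[c];
        }
        if (hi < iso || lo >= iso) continue;
        for (int c = 0; c < 8; ++c) {
          pos[c][0] = (i + CORN[c][0]) * spacing(0);
          pos[c][1] = (j + CORN[c][1]) * spacing(1);
          pos[c][2] = (k + CORN[c][2]) * spacing(2);
        }
        for (int t = 0; t < 6; ++t) {
          const int* tv = TETS[t];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cv[tv[c]] >= iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int a, int b, double* out) {
            const double va = cv[tv[a]], vb = cv[tv[b]];
            const double d = (iso - va) / (vb - va);
            for (int x = 0; x < 3; ++x)
              out[x] = pos[tv[a]][x] + d * (pos[tv[b]][x] - pos[tv[a]][x]);
          };
          auto push = [&](double* p1, double* p2, double* p3) {
            for (int x = 0; x < 3; ++x) tri.push_back(p1[x]);
            for (int x = 0; x < 3; ++x) tri.push_back(p2[x]);
            for (int x = 0; x < 3; ++x) tri.push_back(p3[x]);
            const double ux = p2[0] - p1[0], uy = p2[1] - p1[1],
                         uz = p2[2] - p1[2];
            const double vx = p3[0] - p1[0], vy = p3[1] - p1[1],
                         vz = p3[2] - p1[2];
            const double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
                         cz = ux * vy - uy * vx;
            area += 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
          };
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c)
            (in[c] ? ins[ni++] : outs[no++]) = c;
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1) {
            interp(ins[0], outs[0], p1);
            interp(ins[0], outs[1], p2);
            interp(ins[0], outs[2], p3);
            push(p1, p2, p3);
          } else if (nin == 3) {
            interp(ins[0], outs[0], p1);
            interp(ins[1], outs[0], p2);
            interp(ins[2], outs[0], p3);
            push(p1, p2, p3);
          } else {  // nin == 2: quad split into two triangles
            interp(ins[0], outs[0], p1);
            interp(ins[0], outs[1], p2);
            interp(ins[1], outs[1], p3);
            interp(ins[1], outs[0], p4);
            push(p1, p2, p3);
            push(p1, p3, p4);
          }
        }
      }
  const int ntri = tri.size() / 9;
  mat verts(ntri * 3, 3);
  for (int t = 0; t < ntri * 3; ++t)
    for (int x = 0; x < 3; ++x) verts(t, x) = tri[3 * t + x];
  return Rcpp::List::create(Rcpp::Named("area") = area,
                            Rcpp::Named("n_triangles") = ntri,
                            Rcpp::Named("vertices") = verts);
}

// ---------------- incremental quickhull ----------------

struct Face {
  int v[3];
  vec n;       // outward unit-ish normal (unnormalized)
  double off;  // plane offset: dot(n, x) = off
  bool alive;
  std::vector<int> pts;
};

static inline double vis(const Face& f, const mat& P, const int p) {
  return dot(f.n, P.row(p).t()) - f.off;
}

static void make_face(Face& f, const mat& P, int a, int b, int c,
                      const vec& inner) {
  f.v[0] = a; f.v[1] = b; f.v[2] = c;
  vec u = P.row(b).t() - P.row(a).t();
  vec w = P.row(c).t() - P.row(a).t();
  f.n = cross(u, w);
  f.off = dot(f.n, P.row(a).t());
  if (dot(f.n, inner) - f.off > 0) {  // flip so interior is below plane
    std::swap(f.v[1], f.v[2]);
    f.n = -f.n;
    f.off = -f.off;
  }
  f.alive = true;
}

// [[Rcpp::export]]
Rcpp::List cpp_convex_hull3(const arma::mat& pts) {
  const int n = pts.n_rows;
  if (n < 4) Rcpp::stop("convex hull needs at least 4 points");
  const double scale = std::max(1e-12, as_scalar(max(max(abs(pts), 0), 1)));
  const double eps = 1e-9 * scale;
  // initial extreme points
  uword i0, i1;
  pts.col(0).min(i0);
  pts.col(0).max(i1);
  if (i0 == i1) { pts.col(1).min(i0); pts.col(1).max(i1); }
  if (i0 == i1) { pts.col(2).min(i0); pts.col(2).max(i1); }
  vec a = pts.row(i0).t(), b = pts.row(i1).t();
  int i2 = -1;
  double best = eps;
  for (int p = 0; p < n; ++p) {
    vec d = cross(b - a, pts.row(p).t() - a);
    const double v = norm(d);
    if (v > best) { best = v; i2 = p; }
  }
  if (i2 < 0) Rcpp::stop("degenerate point set (collinear)");
  vec c = pts.row(i2).t();
  vec nrm = cross(b - a, c - a);
  int i3 = -1;
  best = eps * norm(nrm);
  for (int p = 0; p < n; ++p) {
    const double v = std::abs(dot(nrm, pts.row(p).t() - a));
    if (v > best) { best = v; i3 = p; }
  }
  if (i3 < 0) Rcpp::stop("degenerate point set (coplanar)");
  vec inner = (a + b + c + pts.row(i3).t()) / 4.0;

  std::vector<Face> F(4);
  make_face(F[0], pts, i0, i1, i2, inner);
  make_face(F[1], pts, i0, i1, i3, inner);
  make_face(F[2], pts, i0, i2, i3, inner);
  make_face(F[3], pts, i1, i2, i3, inner);
  for (int p = 0; p < n; ++p) {
    if (p == (int)i0 || p == (int)i1 || p == i2 || p == i3) continue;
    for (size_t f = 0; f < F.size(); ++f)
      if (F[f].alive && vis(F[f], pts, p) > eps) {
        F[f].pts.push_back(p);
        break;
      }
  }

  for (;;) {
    int fi = -1;
    for (size_t f = 0; f < F.size(); ++f)
      if (F[f].alive && !F[f].pts.empty()) { fi = f; break; }
    if (fi < 0) break;
    // furthest point above this face
    int pbest = -1;
    double dbest = -1;
    for (int p : F[fi].pts) {
      const double d = vis(F[fi], pts, p);
      if (d > dbest) { dbest = d; pbest = p; }
    }
    // all faces visible from pbest
    std::vector<int> visf;
    for (size_t f = 0; f < F.size(); ++f)
      if (F[f].alive && vis(F[f], pts, pbest) > eps) visf.push_back(f);
    // horizon edges: edges of visible faces not shared with another visible face
    std::vector<std::pair<int, int>> horizon;
    for (int f : visf)
      for (int e = 0; e < 3; ++e) {
        const int va = F[f].v[e], vb = F[f].v[(e + 1) % 3];
        bool shared = false;
        for (int g : visf) {
          if (g == f) continue;
          for (int e2 = 0; e2 < 3; ++e2) {
            const int wa = F[g].v[e2], wb = F[g].v[(e2 + 1) % 3];
            if ((wa == va && wb == vb) || (wa == vb && wb == va)) shared = true;
          }
        }
        if (!shared) horizon.push_back({va, vb});
      }
    // orphaned outside points
    std::vector<int> orphans;
    for (int f : visf) {
      F[f].alive = false;
      for (int p : F[f].pts)
        if (p != pbest) orphans.push_back(p);
      F[f].pts.clear();
    }
    // new faces from horizon to pbest
    std::vector<int> newf;
    for (auto& e : horizon) {
      Face nf;
      make_face(nf, pts, e.first, e.second, pbest, inner);
      F.push_back(nf);
      newf.push_back(F.size() - 1);
    }
    for (int p : orphans)
      for (int f : newf)
        if (vis(F[f], pts, p) > eps) {
          F[f].pts.push_back(p);
          break;
        }
  }

  double area = 0.0, volume = 0.0;
  int nf = 0;
  for (auto& f : F)
    if (f.alive) ++nf;
  mat normals(nf, 3);
  vec offs(nf);
  umat faces(nf, 3);
  int r = 0;
  for (auto& f : F) {
    if (!f.alive) continue;
    const double nn = norm(f.n);
    area += 0.5 * nn;
    // signed tetra volume w.r.t. inner point, outward orientation
    vec pa = pts.row(f.v[0]).t() - inner, pb = pts.row(f.v[1]).t() - inner,
        pc = pts.row(f.v[2]).t() - inner;
    volume += dot(pa, cross(pb, pc)) / 6.0;
    normals.row(r) = (f.n / nn).t();
    offs(r) = f.off / nn;
    faces(r, 0) = f.v[0] + 1; faces(r, 1) = f.v[1] + 1; faces(r, 2) = f.v[2] + 1;
    ++r;
  }
  return Rcpp::List::create(
      Rcpp::Named("area") = area, Rcpp::Named("volume") = volume,
      Rcpp::Named("normals") = normals, Rcpp::Named("offsets") = offs,
      Rcpp::Named("faces") = faces);
}

// Count grid voxels (centers at index*spacing within [lo, hi] index ranges)
// lying inside the hull given by unit normals/offsets; tolerance in mm.
// [[Rcpp::export]]
double cpp_hull_voxel_count(const arma::mat& normals, const arma::vec& offs,
                            const arma::ivec& lo, const arma::ivec& hi,
                            const arma::vec& spacing, const double tol) {
  const int nf = normals.n_rows;
  double count = 0;
  for (int k = lo(2); k <= hi(2); ++k)
    for (int j = lo(1); j <= hi(1); ++j)
      for (int i = lo(0); i <= hi(0); ++i) {
        const double x = i * spacing(0), y = j * spacing(1), z = k * spacing(2);
        bool in = true;
        for (int f = 0; f < nf; ++f) {
          if (normals(f, 0) * x + normals(f, 1) * y + normals(f, 2) * z -
                  offs(f) > tol) {
            in = false;
            break;
          }
        }
        if (in) ++count;
      }
  return count;
}
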