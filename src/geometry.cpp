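#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static inline bool point_in_tri(double px, double py,
                                double ax, double ay,
                                double bx, double by,
                                double cx, double cy) {
  double d1 = cross2(bx - ax, by - ay, px - ax, py - ay);
  double d2 = cross2(cx - bx, cy - by, px - bx, py - by);
  double d3 = cross2(ax - cx, ay - cy, px - cx, py - cy);
  bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(has_neg && has_pos);
}

// Ear-clipping triangulation of a simple polygon.
// Ties are broken by clipping the lowest-index ear first, which keeps the
// result a pure function of the vertex order. Returns 1-based vertex indices.
// [[Rcpp::export]]
IntegerMatrix ear_clip_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) stop("polygon needs at least 3 vertices");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i, 0); y[i] = pts(i, 1); }

  // polygon orientation from the signed area
  double a2 = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a2 += x[i] * y[j] - x[j] * y[i];
  }
  double orient = (a2 >= 0) ? 1.0 : -1.0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  IntegerMatrix tri(n - 2, 3);
  int t = 0;

  while ((int)idx.size() > 3) {
    int m = idx.size();
    int clip = -1;
    // pass 1: proper ears; pass 2: any convex vertex; pass 3: force progress
    for (int pass = 0; pass < 3 && clip < 0; ++pass) {
      for (int k = 0; k < m; ++k) {
        int ip = idx[(k + m - 1) % m], iv = idx[k], in = idx[(k + 1) % m];
        double cr = cross2(x[iv] - x[ip], y[iv] - y[ip],
                           x[in] - x[iv], y[in] - y[iv]) * orient;
        if (pass < 2 && cr <= 1e-14) continue;  // reflex or collinear
        bool ok = true;
        if (pass == 0) {
          for (int q = 0; q < m; ++q) {
            int iq = idx[q];
            if (iq == ip || iq == iv || iq == in) continue;
            if (point_in_tri(x[iq], y[iq], x[ip], y[ip],
                             x[iv], y[iv], x[in], y[in])) { ok = false; break; }
          }
        }
        if (ok) { clip = k; break; }
      }
    }
    int m2 = idx.size();
    int ip = idx[(clip + m2 - 1) % m2], iv = idx[clip], in = idx[(clip + 1) % m2];
    tri(t, 0) = ip + 1; tri(t, 1) = iv + 1; tri(t, 2) = in + 1;
    ++t;
    idx.erase(idx.begin() + clip);
  }
  tri(t, 0) = idx[0] + 1; tri(t, 1) = idx[1] + 1; tri(t, 2) = idx[2] + 1;
  return tri;
}

// Textured-triangle rasterizer with per-pixel Lambert shading:
//   color = albedo * (ambient + intensity * max(0, n_world . light)) * ao
// Leaves are painted in the order given (caller sorts far-to-near); pixels
// are opaque, image origin is top-left, pixel centers at half-integers.
// [[Rcpp::export]]
List rasterize_leaves_cpp(int H, int W, List leaves,
                          NumericVector light_dir,
                          double intensity, double ambient) {
  NumericVector rgb(H * W * 3);
  NumericVector alpha(H * W);
  double Lx = light_dir[0], Ly = light_dir[1], Lz = light_dir[2];

  for (int li = 0; li < leaves.size(); ++li) {
    List lf = leaves[li];
    NumericVector px = lf["px"], py = lf["py"];
    IntegerMatrix tri = lf["tri"];
    NumericVector u = lf["u"], v = lf["v"];
    NumericVector albedo = lf["albedo"], nrm = lf["normal"], ao = lf["ao"];
    NumericVector rot = lf["rot"];  // 3x3 column-major, tangent -> world
    int th = lf["th"], tw = lf["tw"];

    for (int ti = 0; ti < tri.nrow(); ++ti) {
      int ia = tri(ti, 0) - 1, ib = tri(ti, 1) - 1, ic = tri(ti, 2) - 1;
      double ax = px[ia], ay = py[ia], bx = px[ib], by = py[ib],
             cx = px[ic], cy = py[ic];
      double area = cross2(bx - ax, by - ay, cx - ax, cy - ay);
      if (std::fabs(area) < 1e-12) continue;

      double minx = std::min(ax, std::min(bx, cx));
      double maxx = std::max(ax, std::max(bx, cx));
      double miny = std::min(ay, std::min(by, cy));
      double maxy = std::max(ay, std::max(by, cy));
      int j0 = std::max(0, (int)std::floor(minx - 0.5));
      int j1 = std::min(W - 1, (int)std::ceil(maxx - 0.5));
      int i0 = std::max(0, (int)std::floor(miny - 0.5));
      int i1 = std::min(H - 1, (int)std::ceil(maxy - 0.5));

      for (int i = i0; i <= i1; ++i) {
        double pyc = i + 0.5;
        for (int j = j0; j <= j1; ++j) {
          double pxc = j + 0.5;
          double l0 = cross2(cx - bx, cy - by, pxc - bx, pyc - by) / area;
          double l1 = cross2(ax - cx, ay - cy, pxc - cx, pyc - cy) / area;
          double l2 = 1.0 - l0 - l1;
          if (l0 < 0 || l1 < 0 || l2 < 0) continue;

          double uu = l0 * u[ia] + l1 * u[ib] + l2 * u[ic];
          double vv = l0 * v[ia] + l1 * v[ib] + l2 * v[ic];
          int tr = (int)(vv * th); if (tr < 0) tr = 0; if (tr >= th) tr = th - 1;
          int tc = (int)(uu * tw); if (tc < 0) tc = 0; if (tc >= tw) tc = tw - 1;

          double nx = nrm[tr + th * tc];
          double ny = nrm[tr + th * (tc + tw)];
          double nz = nrm[tr + th * (tc + 2 * tw)];
          double wx = rot[0] * nx + rot[3] * ny + rot[6] * nz;
          double wy = rot[1] * nx + rot[4] * ny + rot[7] * nz;
          double wz = rot[2] * nx + rot[5] * ny + rot[8] * nz;
          double nn = std::sqrt(wx * wx + wy * wy + wz * wz);
          if (nn > 0) { wx /= nn; wy /= nn; wz /= nn; }
          double ndl = wx * Lx + wy * Ly + wz * Lz;
          if (ndl < 0) ndl = 0;
          double shade = ambient + intensity * ndl;
          double aov = ao[tr + th * tc];

          int pix = i + H * j;
          for (int k = 0; k < 3; ++k) {
            double cval = albedo[tr + th * (tc + k * tw)] * shade * aov;
            if (cval < 0) cval = 0;
            if (cval > 1) cval = 1;
            rgb[pix + H * W * k] = cval;
          }
          alpha[pix] = 1.0;
        }
      }
    }
  }
  rgb.attr("dim") = Dimension(H, W, 3);
  alpha.attr("dim") = Dimension(H, W);
  return List::create(_["rgb"] = rgb, _["alpha"] = alpha);
}
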