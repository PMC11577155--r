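#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Assemble the sparse circular Radon transform operator.
//
// Row (t, k) integrates a P1 field along the arc of radius radii[k]
// centered at transducer t, clipped to the disk of radius `radius`
// centered at the origin, by composite midpoint quadrature in arc
// length with barycentric interpolation on the triangulation.  Rows are
// transducer-major: row = t * n_radii + k.  Quadrature points falling in
// the sliver between the polygonal mesh boundary and the circle are
// outside the discrete domain and are skipped.
//
// [[Rcpp::export]]
List crt_assemble_cpp(NumericMatrix vertices, IntegerMatrix triangles,
                      NumericMatrix transducers, NumericVector radii,
                      double radius, double step) {
  const int ntri = triangles.nrow();
  const int ntx = transducers.nrow();
  const int nr = radii.size();
  const int nv = vertices.nrow();

  // per-triangle barycentric transforms and bounding boxes
  std::vector<double> p1x(ntri), p1y(ntri), v0x(ntri), v0y(ntri),
      v1x(ntri), v1y(ntri), invdet(ntri),
      bxmin(ntri), bxmax(ntri), bymin(ntri), bymax(ntri);
  for (int t = 0; t < ntri; ++t) {
    int a = triangles(t, 0), b = triangles(t, 1), c = triangles(t, 2);
    double ax = vertices(a, 0), ay = vertices(a, 1);
    double bx = vertices(b, 0), by = vertices(b, 1);
    double cx = vertices(c, 0), cy = vertices(c, 1);
    p1x[t] = ax; p1y[t] = ay;
    v0x[t] = bx - ax; v0y[t] = by - ay;
    v1x[t] = cx - ax; v1y[t] = cy - ay;
    double det = v0x[t] * v1y[t] - v0y[t] * v1x[t];
    invdet[t] = 1.0 / det;
    bxmin[t] = std::min(ax, std::min(bx, cx));
    bxmax[t] = std::max(ax, std::max(bx, cx));
    bymin[t] = std::min(ay, std::min(by, cy));
    bymax[t] = std::max(ay, std::max(by, cy));
  }

  // uniform grid spatial index over the domain bounding box
  double hmax = 0;
  for (int t = 0; t < ntri; ++t)
    hmax = std::max(hmax, std::max(bxmax[t] - bxmin[t], bymax[t] - bymin[t]));
  const double cs = std::max(hmax, 1e-6);
  const double x0 = -radius - cs, y0 = -radius - cs;
  const int ncx = (int)std::ceil((2 * radius + 2 * cs) / cs);
  const int ncy = ncx;
  std::vector<std::vector<int> > cells((size_t)ncx * ncy);
  for (int t = 0; t < ntri; ++t) {
    int ix0 = (int)((bxmin[t] - x0) / cs), ix1 = (int)((bxmax[t] - x0) / cs);
    int iy0 = (int)((bymin[t] - y0) / cs), iy1 = (int)((bymax[t] - y0) / cs);
    for (int ix = std::max(0, ix0); ix <= std::min(ncx - 1, ix1); ++ix)
      for (int iy = std::max(0, iy0); iy <= std::min(ncy - 1, iy1); ++iy)
        cells[(size_t)ix * ncy + iy].push_back(t);
  }

  std::vector<int> out_i, out_j;
  std::vector<double> out_x;
  std::vector<double> acc(nv, 0.0);
  std::vector<int> touched;
  touched.reserve(1024);
  const double tol = -1e-10;

  for (int tx = 0; tx < ntx; ++tx) {
    double sx = transducers(tx, 0), sy = transducers(tx, 1);
    double L = std::sqrt(sx * sx + sy * sy);
    double thc = std::atan2(-sy, -sx);
    for (int k = 0; k < nr; ++k) {
      double rho = radii[k];
      if (rho <= L - radius || rho >= L + radius || rho <= 0) continue;
      double cpsi = (L * L + rho * rho - radius * radius) / (2 * L * rho);
      if (cpsi > 1) cpsi = 1; if (cpsi < -1) cpsi = -1;
      double psi = std::acos(cpsi);
      if (psi <= 0) continue;
      int nq = (int)std::ceil(2 * psi * rho / step);
      if (nq < 1) nq = 1;
      double dth = 2 * psi / nq;
      double w = rho * dth;
      for (int m = 0; m < nq; ++m) {
        double th = thc - psi + (m + 0.5) * dth;
        double px = sx + rho * std::cos(th);
        double py = sy + rho * std::sin(th);
        if (px * px + py * py > radius * radius) continue;
        int ix = (int)((px - x0) / cs), iy = (int)((py - y0) / cs);
        if (ix < 0 || ix >= ncx || iy < 0 || iy >= ncy) continue;
        const std::vector<int>& cand = cells[(size_t)ix * ncy + iy];
        for (size_t ci = 0; ci < cand.size(); ++ci) {
          int t = cand[ci];
          if (px < bxmin[t] || px > bxmax[t] || py < bymin[t] || py > bymax[t])
            continue;
          double rx = px - p1x[t], ry = py - p1y[t];
          double l2 = (rx * v1y[t] - ry * v1x[t]) * invdet[t];
          if (l2 < tol || l2 > 1 - tol) continue;
          double l3 = (v0x[t] * ry - v0y[t] * rx) * invdet[t];
          if (l3 < tol || l2 + l3 > 1 - tol) continue;
          double l1 = 1 - l2 - l3;
          int a = triangles(t, 0), b = triangles(t, 1), c = triangles(t, 2);
          if (acc[a] == 0) touched.push_back(a);
          acc[a] += w * l1;
          if (acc[b] == 0) touched.push_back(b);
          acc[b] += w * l2;
          if (acc[c] == 0) touched.push_back(c);
          acc[c] += w * l3;
          break;
        }
      }
      if (!touched.empty()) {
        int row = tx * nr + k + 1;  // 1-based for R
        for (size_t u = 0; u < touched.size(); ++u) {
          int node = touched[u];
          if (acc[node] != 0.0) {
            out_i.push_back(row);
            out_j.push_back(node + 1);
            out_x.push_back(acc[node]);
            acc[node] = 0.0;
          }
        }
        touched.clear();
      }
    }
  }
  return List::create(Named("i") = wrap(out_i), Named("j") = wrap(out_j),
                      Named("x") = wrap(out_x));
}
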