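#include <Rcpp.h>
using namespace Rcpp;

// Exact P1 trilinear reaction form: out_k = d/da_k [ p^T M(a) phi ].
// The tensor int_T phi_i phi_j phi_k is fully symmetric, so the same
// kernel evaluates M(a) phi for a P1 coefficient a.
//
// [[Rcpp::export]]
NumericVector fem_mass_trilinear(IntegerMatrix tri, NumericVector area,
                                 NumericVector p, NumericVector phi,
                                 int n_nodes) {
  NumericVector out(n_nodes);
  const int M = tri.nrow();
  for (int t = 0; t < M; ++t) {
    int n0 = tri(t, 0), n1 = tri(t, 1), n2 = tri(t, 2);
    double A = area[t];
    double p0 = p[n0], p1 = p[n1], p2 = p[n2];
    double f0 = phi[n0], f1 = phi[n1], f2 = phi[n2];
    out[n0] += A * (p0 * f0 / 10 +
                    (p0 * (f1 + f2) + f0 * (p1 + p2) + p1 * f1 + p2 * f2) / 30 +
                    (p1 * f2 + p2 * f1) / 60);
    out[n1] += A * (p1 * f1 / 10 +
                    (p1 * (f2 + f0) + f1 * (p2 + p0) + p2 * f2 + p0 * f0) / 30 +
                    (p2 * f0 + p0 * f2) / 60);
    out[n2] += A * (p2 * f2 / 10 +
                    (p2 * (f0 + f1) + f2 * (p0 + p1) + p0 * f0 + p1 * f1) / 30 +
                    (p0 * f1 + p1 * f0) / 60);
  }
  return out;
}

// Derivative of the element-mean-coefficient stiffness form:
// out_k = d/db_k [ p^T K(bbar) phi ] = sum_{T owning k} |T| grad p . grad phi / 3
//
// [[Rcpp::export]]
NumericVector fem_stiff_trilinear(IntegerMatrix tri, NumericVector area,
                                  NumericMatrix gb, NumericMatrix gc,
                                  NumericVector p, NumericVector phi,
                                  int n_nodes) {
  NumericVector out(n_nodes);
  const int M = tri.nrow();
  for (int t = 0; t < M; ++t) {
    int n0 = tri(t, 0), n1 = tri(t, 1), n2 = tri(t, 2);
    double gpx = gb(t, 0) * p[n0] + gb(t, 1) * p[n1] + gb(t, 2) * p[n2];
    double gpy = gc(t, 0) * p[n0] + gc(t, 1) * p[n1] + gc(t, 2) * p[n2];
    double gfx = gb(t, 0) * phi[n0] + gb(t, 1) * phi[n1] + gb(t, 2) * phi[n2];
    double gfy = gc(t, 0) * phi[n0] + gc(t, 1) * phi[n1] + gc(t, 2) * phi[n2];
    double gg = (gpx * gfx + gpy * gfy) / (12 * area[t]);
    out[n0] += gg; out[n1] += gg; out[n2] += gg;
  }
  return out;
}

// K(bbar) phi with bbar the element mean of the nodal coefficient b.
//
// [[Rcpp::export]]
NumericVector fem_stiff_apply(IntegerMatrix tri, NumericVector area,
                              NumericMatrix gb, NumericMatrix gc,
                              NumericVector b, NumericVector phi,
                              int n_nodes) {
  NumericVector out(n_nodes);
  const int M = tri.nrow();
  for (int t = 0; t < M; ++t) {
    int n0 = tri(t, 0), n1 = tri(t, 1), n2 = tri(t, 2);
    double bl = (b[n0] + b[n1] + b[n2]) / 3;
    double gfx = gb(t, 0) * phi[n0] + gb(t, 1) * phi[n1] + gb(t, 2) * phi[n2];
    double gfy = gc(t, 0) * phi[n0] + gc(t, 1) * phi[n1] + gc(t, 2) * phi[n2];
    double w = bl / (4 * area[t]);
    out[n0] += w * (gb(t, 0) * gfx + gc(t, 0) * gfy);
    out[n1] += w * (gb(t, 1) * gfx + gc(t, 1) * gfy);
    out[n2] += w * (gb(t, 2) * gfx + gc(t, 2) * gfy);
  }
  return out;
}
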