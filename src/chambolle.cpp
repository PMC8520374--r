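// Chambolle-type dual projected-gradient iterations for the weighted
// isotropic TV proximal operator
//   argmin_u 0.5 ||u - z||^2 + theta * sum_v w_v ||grad u(v)||
// on a 3D voxel grid (singleton axes allowed). The gradient is the forward
// difference with replicate (Neumann) boundary, matching spatial_gradient()
// on the R side; the divergence is its negative adjoint.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
List chambolle_wtv(NumericVector z, NumericVector w, double theta,
                   int iters, NumericVector p) {
  IntegerVector dz = z.attr("dim");
  const int nx = dz[0], ny = dz[1], nz = dz[2];
  const int n = nx * ny * nz;

  int active = (nx > 1) + (ny > 1) + (nz > 1);
  if (active == 0) active = 1;
  const double tau = 1.0 / (4.0 * active);

  std::vector<double> div(n), s(n), gx(n), gy(n), gz(n);
  // p components stored contiguously: p[0..n-1] axis 1, etc.
  NumericVector pc = clone(p);   // do not mutate the caller's warm start
  double *p1 = REAL(pc), *p2 = REAL(pc) + n, *p3 = REAL(pc) + 2 * n;
  const double *zp = REAL(z), *wp = REAL(w);

  for (int it = 0; it < iters; ++it) {
    // divergence of p
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int v = idx3(i, j, k, nx, ny);
          double dv = 0.0;
          if (nx > 1) {
            if (i < nx - 1) dv += p1[v];
            if (i > 0)      dv -= p1[idx3(i - 1, j, k, nx, ny)];
          }
          if (ny > 1) {
            if (j < ny - 1) dv += p2[v];
            if (j > 0)      dv -= p2[idx3(i, j - 1, k, nx, ny)];
          }
          if (nz > 1) {
            if (k < nz - 1) dv += p3[v];
            if (k > 0)      dv -= p3[idx3(i, j, k - 1, nx, ny)];
          }
          div[v] = dv;
        }
    for (int v = 0; v < n; ++v) s[v] = div[v] - zp[v] / theta;
    // forward-difference gradient of s
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int v = idx3(i, j, k, nx, ny);
          gx[v] = (nx > 1 && i < nx - 1) ? s[idx3(i + 1, j, k, nx, ny)] - s[v] : 0.0;
          gy[v] = (ny > 1 && j < ny - 1) ? s[idx3(i, j + 1, k, nx, ny)] - s[v] : 0.0;
          gz[v] = (nz > 1 && k < nz - 1) ? s[idx3(i, j, k + 1, nx, ny)] - s[v] : 0.0;
        }
    // semi-implicit dual update with per-voxel radius w_v
    for (int v = 0; v < n; ++v) {
      const double gn = std::sqrt(gx[v] * gx[v] + gy[v] * gy[v] + gz[v] * gz[v]);
      const double denom = 1.0 + tau * gn / wp[v];
      p1[v] = (p1[v] + tau * gx[v]) / denom;
      p2[v] = (p2[v] + tau * gy[v]) / denom;
      p3[v] = (p3[v] + tau * gz[v]) / denom;
    }
  }

  // primal recovery u = z - theta * div(p)
  NumericVector u(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        double dv = 0.0;
        if (nx > 1) {
          if (i < nx - 1) dv += p1[v];
          if (i > 0)      dv -= p1[idx3(i - 1, j, k, nx, ny)];
        }
        if (ny > 1) {
          if (j < ny - 1) dv += p2[v];
          if (j > 0)      dv -= p2[idx3(i, j - 1, k, nx, ny)];
        }
        if (nz > 1) {
          if (k < nz - 1) dv += p3[v];
          if (k > 0)      dv -= p3[idx3(i, j, k - 1, nx, ny)];
        }
        u[v] = zp[v] - theta * dv;
      }
  u.attr("dim") = dz;
  return List::create(_["u"] = u, _["p"] = pc);
}
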