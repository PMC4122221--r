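#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cell-centered finite-volume operator on a regular voxel grid:
// (A phi)_v = sum_faces g_f * (phi_v - phi_nbr), with face conductances
// gx, gy, gz (siemens) stored on the (n-1) faces along each axis.
// Non-conductive voxels (mask false) carry zero coupling and are held at 0.

static void apply_stencil(const double* gx, const double* gy, const double* gz,
                          const int* mask, const double* x, double* y,
                          int nx, int ny, int nz) {
  const int nxm = nx - 1;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      const R_xlen_t bx = (R_xlen_t)nxm * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = base + i;
        if (!mask[v]) { y[v] = 0.0; continue; }
        double acc = 0.0;
        if (i > 0)      { double g = gx[bx + i - 1];            if (g > 0) acc += g * (x[v] - x[v - 1]); }
        if (i < nx - 1) { double g = gx[bx + i];                if (g > 0) acc += g * (x[v] - x[v + 1]); }
        if (j > 0)      { double g = gy[(R_xlen_t)nx * (j - 1 + (R_xlen_t)(ny - 1) * k) + i];
                          if (g > 0) acc += g * (x[v] - x[v - nx]); }
        if (j < ny - 1) { double g = gy[(R_xlen_t)nx * (j + (R_xlen_t)(ny - 1) * k) + i];
                          if (g > 0) acc += g * (x[v] - x[v + nx]); }
        if (k > 0)      { double g = gz[(R_xlen_t)nx * (j + (R_xlen_t)ny * (k - 1)) + i];
                          if (g > 0) acc += g * (x[v] - x[v - (R_xlen_t)nx * ny]); }
        if (k < nz - 1) { double g = gz[(R_xlen_t)nx * (j + (R_xlen_t)ny * k) + i];
                          if (g > 0) acc += g * (x[v] - x[v + (R_xlen_t)nx * ny]); }
        y[v] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".apply_stencil_cpp")]]
NumericVector apply_stencil_cpp(NumericVector gx, NumericVector gy,
                                NumericVector gz, LogicalVector mask,
                                NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector y(x.size());
  apply_stencil(REAL(gx), REAL(gy), REAL(gz), LOGICAL(mask), REAL(x),
                REAL(y), nx, ny, nz);
  y.attr("dim") = dims;
  return y;
}

// Jacobi-preconditioned conjugate gradients for the singular (pure-Neumann)
// system; the one-dimensional null space (constants on the conductive set) is
// handled by projecting iterates onto the zero-mean subspace each iteration.
// [[Rcpp::export(name = ".cg_solve_cpp")]]
List cg_solve_cpp(NumericVector gx, NumericVector gy, NumericVector gz,
                  LogicalVector mask, NumericVector b, IntegerVector dims,
                  double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  const double* bp = REAL(b);

  std::vector<double> diag(n, 0.0);
  {
    // diagonal of A: sum of incident face conductances
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (!m[v]) continue;
          double d = 0.0;
          if (i > 0)      d += REAL(gx)[(R_xlen_t)(nx-1) * (j + (R_xlen_t)ny * k) + i - 1];
          if (i < nx - 1) d += REAL(gx)[(R_xlen_t)(nx-1) * (j + (R_xlen_t)ny * k) + i];
          if (j > 0)      d += REAL(gy)[(R_xlen_t)nx * (j - 1 + (R_xlen_t)(ny-1) * k) + i];
          if (j < ny - 1) d += REAL(gy)[(R_xlen_t)nx * (j + (R_xlen_t)(ny-1) * k) + i];
          if (k > 0)      d += REAL(gz)[(R_xlen_t)nx * (j + (R_xlen_t)ny * (k-1)) + i];
          if (k < nz - 1) d += REAL(gz)[(R_xlen_t)nx * (j + (R_xlen_t)ny * k) + i];
          diag[v] = d;
        }
  }

  R_xlen_t ncond = 0;
  for (R_xlen_t v = 0; v < n; ++v) if (m[v]) ++ncond;
  if (ncond == 0) stop("no conductive voxels");

  std::vector<double> x(n, 0.0), r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0);
  double bnorm2 = 0.0;
  for (R_xlen_t v = 0; v < n; ++v) {
    r[v] = m[v] ? bp[v] : 0.0;
    bnorm2 += r[v] * r[v];
  }
  const double bnorm = std::sqrt(bnorm2);
  double relres = 1.0;
  int iter = 0;
  bool converged = (bnorm == 0.0);

  auto project = [&](std::vector<double>& w) {
    double s = 0.0;
    for (R_xlen_t v = 0; v < n; ++v) if (m[v]) s += w[v];
    s /= (double)ncond;
    for (R_xlen_t v = 0; v < n; ++v) if (m[v]) w[v] -= s;
  };

  if (!converged) {
    project(r);
    double rz = 0.0;
    for (R_xlen_t v = 0; v < n; ++v) {
      z[v] = (m[v] && diag[v] > 0) ? r[v] / diag[v] : 0.0;
      rz += r[v] * z[v];
      p[v] = z[v];
    }
    for (iter = 1; iter <= maxit; ++iter) {
      apply_stencil(REAL(gx), REAL(gy), REAL(gz), m, p.data(), Ap.data(),
                    nx, ny, nz);
      double pAp = 0.0;
      for (R_xlen_t v = 0; v < n; ++v) pAp += p[v] * Ap[v];
      if (pAp <= 0) break;
      double alpha = rz / pAp;
      double rnorm2 = 0.0;
      for (R_xlen_t v = 0; v < n; ++v) {
        x[v] += alpha * p[v];
        r[v] -= alpha * Ap[v];
      }
      project(r);
      project(x);
      for (R_xlen_t v = 0; v < n; ++v) rnorm2 += r[v] * r[v];
      relres = std::sqrt(rnorm2) / bnorm;
      if (relres <= tol) { converged = true; break; }
      double rz_new = 0.0;
      for (R_xlen_t v = 0; v < n; ++v) {
        z[v] = (m[v] && diag[v] > 0) ? r[v] / diag[v] : 0.0;
        rz_new += r[v] * z[v];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (R_xlen_t v = 0; v < n; ++v) p[v] = z[v] + beta * p[v];
    }
  }

  NumericVector phi(n);
  for (R_xlen_t v = 0; v < n; ++v) phi[v] = x[v];
  phi.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = converged);
}
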