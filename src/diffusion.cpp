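#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Matrix-free 7-point operator for the steady diffusion equation
//   -div(D grad phi) + mua phi = S
// on a cell-centered grid with Robin walls: outward flux through a
// boundary face equals alpha * phi_cell with
//   alpha = hb * 2D / (hb*h + 2D)
// (from eliminating the face value of -D dphi/dn = hb * phi_face).
// Units: D and h in mm, mua in 1/mm; the operator is symmetric positive
// definite, so plain conjugate gradients applies.

static inline void apply_op(const std::vector<double> &x,
                            std::vector<double> &y,
                            int nx, int ny, int nz,
                            double D, double mua, double h, double alpha) {
  const double w = D / (h * h);
  const double bfac = alpha / h;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + i;
        double xc = x[idx];
        double acc = mua * xc;
        if (i > 0)      acc += w * (xc - x[idx - sx]); else acc += bfac * xc;
        if (i < nx - 1) acc += w * (xc - x[idx + sx]); else acc += bfac * xc;
        if (j > 0)      acc += w * (xc - x[idx - sy]); else acc += bfac * xc;
        if (j < ny - 1) acc += w * (xc - x[idx + sy]); else acc += bfac * xc;
        if (k > 0)      acc += w * (xc - x[idx - sz]); else acc += bfac * xc;
        if (k < nz - 1) acc += w * (xc - x[idx + sz]); else acc += bfac * xc;
        y[idx] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".diffusion_apply")]]
NumericVector diffusion_apply(NumericVector x, int nx, int ny, int nz,
                              double D, double mua, double h, double hb) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("size mismatch");
  double alpha = hb * 2.0 * D / (hb * h + 2.0 * D);
  std::vector<double> xin(x.begin(), x.end()), y(n);
  apply_op(xin, y, nx, ny, nz, D, mua, h, alpha);
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export(name = ".diffusion_solve_cg")]]
List diffusion_solve_cg(NumericVector src, int nx, int ny, int nz,
                        double D, double mua, double h, double hb,
                        double tol, int maxit) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (src.size() != n) stop("source size mismatch");
  double alpha = hb * 2.0 * D / (hb * h + 2.0 * D);
  std::vector<double> b(src.begin(), src.end());
  std::vector<double> x(n, 0.0), r(b), p(b), Ap(n);

  double bnorm = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["phi"] = NumericVector(n),
                        _["iterations"] = 0, _["relres"] = 0.0);
  }
  double rs = bnorm * bnorm;
  int it = 0;
  double relres = 1.0;
  for (it = 0; it < maxit; ++it) {
    apply_op(p, Ap, nx, ny, nz, D, mua, h, alpha);
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    double a = rs / pAp;
    double rs_new = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      x[i] += a * p[i];
      r[i] -= a * Ap[i];
      rs_new += r[i] * r[i];
    }
    relres = std::sqrt(rs_new) / bnorm;
    if (relres < tol) { rs = rs_new; ++it; break; }
    double beta = rs_new / rs;
    rs = rs_new;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (relres >= tol) {
    stop("conjugate-gradient solve did not converge: relres = %g after %d iterations",
         relres, it);
  }
  return List::create(_["phi"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["relres"] = relres);
}
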