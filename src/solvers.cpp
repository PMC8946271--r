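#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Flux-conservative 7-point stencil for  -div(a grad u) + s u = f  on a
// regular voxel grid, with Dirichlet voxels held at fixed values and
// homogeneous Neumann (zero-flux) behaviour on any free face that touches
// the domain edge.  Face coefficients are harmonic means of the two cell
// coefficients times area/distance, so the matrix is complex symmetric
// (real SPD when all inputs are real and s >= 0).

static inline cplx hmean(const cplx &x, const cplx &y) {
  cplx s = x + y;
  if (std::abs(s) == 0.0) return cplx(0.0, 0.0);
  return 2.0 * x * y / s;
}

struct Stencil {
  int nx, ny, nz;
  size_t n;
  // face coefficients: wx[idx] couples idx and idx+1 in x (size n, last slab unused)
  std::vector<cplx> wx, wy, wz;
  std::vector<cplx> diag;      // sum of face couplings + sink term
  const int *fixed;            // 1 = Dirichlet
  inline size_t at(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
  // y = A u restricted to free voxels; Dirichlet entries of u are ignored
  // (their contribution is pre-moved to the RHS).
  void apply(const std::vector<cplx> &u, std::vector<cplx> &y) const {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t p = at(i, j, k);
          if (fixed[p]) { y[p] = cplx(0, 0); continue; }
          cplx acc = diag[p] * u[p];
          if (i > 0)      { size_t q = p - 1;                      if (!fixed[q]) acc -= wx[q] * u[q]; }
          if (i < nx - 1) { size_t q = p + 1;                      if (!fixed[q]) acc -= wx[p] * u[q]; }
          if (j > 0)      { size_t q = p - (size_t)nx;             if (!fixed[q]) acc -= wy[q] * u[q]; }
          if (j < ny - 1) { size_t q = p + (size_t)nx;             if (!fixed[q]) acc -= wy[p] * u[q]; }
          if (k > 0)      { size_t q = p - (size_t)nx * ny;        if (!fixed[q]) acc -= wz[q] * u[q]; }
          if (k < nz - 1) { size_t q = p + (size_t)nx * ny;        if (!fixed[q]) acc -= wz[p] * u[q]; }
          y[p] = acc;
        }
  }
};

// [[Rcpp::export(name = ".stencil_solve_cpp")]]
List stencil_solve_cpp(IntegerVector dims, NumericVector spacing_m,
                       ComplexVector a_cell, NumericVector sink_cell,
                       ComplexVector src_cell, IntegerVector dirichlet,
                       ComplexVector u_fixed, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)a_cell.size() != n || (size_t)sink_cell.size() != n ||
      (size_t)src_cell.size() != n || (size_t)dirichlet.size() != n ||
      (size_t)u_fixed.size() != n)
    stop("stencil_solve: field lengths do not match grid dims");

  const double hx = spacing_m[0], hy = spacing_m[1], hz = spacing_m[2];
  const double vol = hx * hy * hz;
  const double fx = hy * hz / hx, fy = hx * hz / hy, fz = hx * hy / hz;

  Stencil S;
  S.nx = nx; S.ny = ny; S.nz = nz; S.n = n;
  S.fixed = INTEGER(dirichlet);
  S.wx.assign(n, cplx(0, 0)); S.wy.assign(n, cplx(0, 0)); S.wz.assign(n, cplx(0, 0));
  S.diag.assign(n, cplx(0, 0));

  std::vector<cplx> a(n);
  for (size_t p = 0; p < n; ++p) a[p] = cplx(a_cell[p].r, a_cell[p].i);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = S.at(i, j, k);
        if (i < nx - 1) S.wx[p] = fx * hmean(a[p], a[p + 1]);
        if (j < ny - 1) S.wy[p] = fy * hmean(a[p], a[p + (size_t)nx]);
        if (k < nz - 1) S.wz[p] = fz * hmean(a[p], a[p + (size_t)nx * ny]);
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = S.at(i, j, k);
        cplx d = sink_cell[p] * vol;
        if (i > 0)      d += S.wx[p - 1];
        if (i < nx - 1) d += S.wx[p];
        if (j > 0)      d += S.wy[p - (size_t)nx];
        if (j < ny - 1) d += S.wy[p];
        if (k > 0)      d += S.wz[p - (size_t)nx * ny];
        if (k < nz - 1) d += S.wz[p];
        S.diag[p] = d;
      }

  // right-hand side: source term plus Dirichlet neighbour contributions
  std::vector<cplx> b(n, cplx(0, 0)), uf(n);
  for (size_t p = 0; p < n; ++p) uf[p] = cplx(u_fixed[p].r, u_fixed[p].i);
  size_t nfix = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = S.at(i, j, k);
        if (S.fixed[p]) { ++nfix; continue; }
        cplx acc = cplx(src_cell[p].r, src_cell[p].i) * vol;
        if (i > 0)      { size_t q = p - 1;               if (S.fixed[q]) acc += S.wx[q] * uf[q]; }
        if (i < nx - 1) { size_t q = p + 1;               if (S.fixed[q]) acc += S.wx[p] * uf[q]; }
        if (j > 0)      { size_t q = p - (size_t)nx;      if (S.fixed[q]) acc += S.wy[q] * uf[q]; }
        if (j < ny - 1) { size_t q = p + (size_t)nx;      if (S.fixed[q]) acc += S.wy[p] * uf[q]; }
        if (k > 0)      { size_t q = p - (size_t)nx * ny; if (S.fixed[q]) acc += S.wz[q] * uf[q]; }
        if (k < nz - 1) { size_t q = p + (size_t)nx * ny; if (S.fixed[q]) acc += S.wz[p] * uf[q]; }
        b[p] = acc;
      }
  if (nfix == 0) stop("stencil_solve: no Dirichlet voxels; system is singular");

  // Jacobi-preconditioned COCG (complex symmetric); reduces to PCG for
  // real SPD input.  Unconjugated inner products throughout.
  std::vector<cplx> x(n, cplx(0, 0)), r(b), z(n), pv(n, cplx(0, 0)), q(n);
  double bnorm = 0.0;
  for (size_t p = 0; p < n; ++p) if (!S.fixed[p]) bnorm += std::norm(r[p]);
  bnorm = std::sqrt(bnorm);
  double relres = 0.0;
  int it = 0;
  bool converged = (bnorm == 0.0);
  if (!converged) {
    cplx rho(0, 0);
    for (size_t p = 0; p < n; ++p) {
      if (S.fixed[p]) { z[p] = cplx(0, 0); continue; }
      cplx d = S.diag[p];
      z[p] = (std::abs(d) > 0.0) ? r[p] / d : r[p];
      rho += r[p] * z[p];
    }
    pv = z;
    for (it = 1; it <= maxit; ++it) {
      S.apply(pv, q);
      cplx pq(0, 0);
      for (size_t p = 0; p < n; ++p) if (!S.fixed[p]) pq += pv[p] * q[p];
      if (std::abs(pq) == 0.0) break;  // breakdown
      cplx alpha = rho / pq;
      double rnorm = 0.0;
      for (size_t p = 0; p < n; ++p) {
        if (S.fixed[p]) continue;
        x[p] += alpha * pv[p];
        r[p] -= alpha * q[p];
        rnorm += std::norm(r[p]);
      }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres < tol) { converged = true; break; }
      cplx rho_new(0, 0);
      for (size_t p = 0; p < n; ++p) {
        if (S.fixed[p]) continue;
        cplx d = S.diag[p];
        z[p] = (std::abs(d) > 0.0) ? r[p] / d : r[p];
        rho_new += r[p] * z[p];
      }
      if (std::abs(rho) == 0.0) break;
      cplx beta = rho_new / rho;
      rho = rho_new;
      for (size_t p = 0; p < n; ++p) if (!S.fixed[p]) pv[p] = z[p] + beta * pv[p];
    }
  }

  ComplexVector out(n);
  for (size_t p = 0; p < n; ++p) {
    cplx v = S.fixed[p] ? uf[p] : x[p];
    out[p].r = v.real(); out[p].i = v.imag();
  }
  return List::create(_["u"] = out, _["iterations"] = it,
                      _["relative_residual"] = relres,
                      _["converged"] = converged);
}

static inline double trilinear(const double *f, int nx, int ny, int nz,
                               double x, double y, double z, bool &ok) {
  // x, y, z in voxel-index units (0-based)
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false; return 0.0;
  }
  ok = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double tx = x - i0, ty = y - j0, tz = z - k0;
  size_t sxy = (size_t)nx * ny;
  size_t p000 = (size_t)i0 + (size_t)nx * j0 + sxy * k0;
  int di = (nx > 1) ? 1 : 0, dj = (ny > 1) ? nx : 0;
  size_t dk = (nz > 1) ? sxy : 0;
  double c00 = f[p000] * (1 - tx) + f[p000 + di] * tx;
  double c10 = f[p000 + dj] * (1 - tx) + f[p000 + dj + di] * tx;
  double c01 = f[p000 + dk] * (1 - tx) + f[p000 + dk + di] * tx;
  double c11 = f[p000 + dk + dj] * (1 - tx) + f[p000 + dk + dj + di] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export(name = ".gamma_index_cpp")]]
NumericVector gamma_index_cpp(NumericVector ref, NumericVector eval,
                              IntegerVector dims, NumericVector spacing_mm,
                              double crit_abs, double dta_mm,
                              double search_radius_mm, double step_mm,
                              IntegerVector analyse) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const double sx = spacing_mm[0], sy = spacing_mm[1], sz = spacing_mm[2];

  // candidate offsets on a step_mm lattice inside the search sphere,
  // sorted by distance for early termination
  struct Off { double dx, dy, dz, d2; };
  std::vector<Off> offs;
  int mx = (int)std::floor(search_radius_mm / step_mm);
  for (int a = -mx; a <= mx; ++a)
    for (int b = -mx; b <= mx; ++b)
      for (int c = -mx; c <= mx; ++c) {
        double dx = a * step_mm, dy = b * step_mm, dz = c * step_mm;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= search_radius_mm * search_radius_mm + 1e-12)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &u, const Off &v) { return u.d2 < v.d2; });

  const double *rf = REAL(ref);
  NumericVector gamma_out(n, NA_REAL);
  const double dta2 = dta_mm * dta_mm, crit2 = crit_abs * crit_abs;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t p = (size_t)i + (size_t)nx * j + (size_t)nx * ny * k;
        if (!analyse[p]) continue;
        double e = eval[p];
        double best = std::numeric_limits<double>::infinity();
        for (const Off &o : offs) {
          double dist_term = o.d2 / dta2;
          if (dist_term >= best) break;  // offsets sorted by distance
          bool ok;
          double rv = trilinear(rf, nx, ny, nz,
                                i + o.dx / sx, j + o.dy / sy, k + o.dz / sz, ok);
          if (!ok) continue;
          double diff = e - rv;
          double g2 = diff * diff / crit2 + dist_term;
          if (g2 < best) best = g2;
        }
        gamma_out[p] = std::sqrt(best);
      }
  return gamma_out;
}
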