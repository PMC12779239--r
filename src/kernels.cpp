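#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Kraskov (KSG algorithm 1) mutual information between 3-D node vectors.
// flat: n_samples x (3 * n_nodes), columns ordered x(all nodes), y(...), z(...)
// ---------------------------------------------------------------------------

static double ksg_pair(const NumericMatrix& flat, int n_nodes, int a, int b,
                       int k) {
  const int n = flat.nrow();
  const double* ax = &flat(0, a);
  const double* ay = &flat(0, a + n_nodes);
  const double* az = &flat(0, a + 2 * n_nodes);
  const double* bx = &flat(0, b);
  const double* by = &flat(0, b + n_nodes);
  const double* bz = &flat(0, b + 2 * n_nodes);

  std::vector<double> dx(n), dy(n), dz(n), tmp(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d1 = std::fabs(ax[i] - ax[j]);
      double d2 = std::fabs(ay[i] - ay[j]);
      if (d2 > d1) d1 = d2;
      d2 = std::fabs(az[i] - az[j]);
      if (d2 > d1) d1 = d2;
      dx[j] = d1;
      double e1 = std::fabs(bx[i] - bx[j]);
      double e2 = std::fabs(by[i] - by[j]);
      if (e2 > e1) e1 = e2;
      e2 = std::fabs(bz[i] - bz[j]);
      if (e2 > e1) e1 = e2;
      dy[j] = e1;
      dz[j] = (d1 > e1) ? d1 : e1;
    }
    dz[i] = R_PosInf;  // exclude self
    tmp = dz;
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_ksg_mi_matrix(NumericMatrix flat, int n_nodes, int k) {
  NumericMatrix mi(n_nodes, n_nodes);
  for (int a = 0; a < n_nodes; ++a) {
    for (int b = a + 1; b < n_nodes; ++b) {
      double v = ksg_pair(flat, n_nodes, a, b, k);
      mi(a, b) = v;
      mi(b, a) = v;
    }
  }
  return mi;
}

// [[Rcpp::export]]
double cpp_ksg_mi(NumericMatrix x, NumericMatrix y, int k) {
  // generic KSG-1 for two multivariate series (used for cross-checks)
  const int n = x.nrow();
  std::vector<double> dx(n), dy(n), dz(n), tmp(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d1 = 0.0;
      for (int c = 0; c < x.ncol(); ++c) {
        double d = std::fabs(x(i, c) - x(j, c));
        if (d > d1) d1 = d;
      }
      double e1 = 0.0;
      for (int c = 0; c < y.ncol(); ++c) {
        double d = std::fabs(y(i, c) - y(j, c));
        if (d > e1) e1 = d;
      }
      dx[j] = d1; dy[j] = e1; dz[j] = (d1 > e1) ? d1 : e1;
    }
    dz[i] = R_PosInf;
    tmp = dz;
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double)k) + R::digamma((double)n) - acc / n;
  return mi > 0.0 ? mi : 0.0;
}

// ---------------------------------------------------------------------------
// Shrake-Rupley solvent-accessible surface area with deterministic
// golden-spiral sphere points. radii: intrinsic atom radii (nm).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix X, NumericVector radii, double probe,
                       int n_points) {
  const int n = X.nrow();
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  for (int s = 0; s < n_points; ++s) {
    double z = 1.0 - 2.0 * (s + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * s;
    px[s] = r * std::cos(phi);
    py[s] = r * std::sin(phi);
    pz[s] = z;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    // neighbour list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = X(j, 0) - X(i, 0), dy = X(j, 1) - X(i, 1),
             dz = X(j, 2) - X(i, 2);
      if (dx * dx + dy * dy + dz * dz < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int s = 0; s < n_points; ++s) {
      double qx = X(i, 0) + ri * px[s];
      double qy = X(i, 1) + ri * py[s];
      double qz = X(i, 2) + ri * pz[s];
      bool free_pt = true;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double rj = radii[j] + probe;
        double dx = qx - X(j, 0), dy = qy - X(j, 1), dz = qz - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return area;
}

// ---------------------------------------------------------------------------
// Finite-difference linearized Poisson-Boltzmann solver.
// 7-point stencil, harmonic-mean face dielectrics (edge-fraction sampling of
// the sphere-union solute volume), Debye-Hueckel Dirichlet boundary, SOR.
// Units: nm, elementary charges; phi in kJ/mol/e; energies kJ/mol.
// ---------------------------------------------------------------------------

struct Grid {
  int nx, ny, nz;
  double lo[3], h;
  inline long id(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
};

static inline bool inside_solute(double x, double y, double z,
                                 const NumericMatrix& X,
                                 const NumericVector& radii) {
  for (int a = 0; a < X.nrow(); ++a) {
    double dx = x - X(a, 0), dy = y - X(a, 1), dz = z - X(a, 2);
    if (dx * dx + dy * dy + dz * dz <= radii[a] * radii[a]) return true;
  }
  return false;
}

static double face_eps(double x0, double y0, double z0, double x1, double y1,
                       double z1, const NumericMatrix& X,
                       const NumericVector& radii, double eps_in,
                       double eps_out) {
  const int S = 3;
  int cnt = 0;
  for (int s = 0; s < S; ++s) {
    double t = (s + 0.5) / S;
    if (inside_solute(x0 + t * (x1 - x0), y0 + t * (y1 - y0),
                      z0 + t * (z1 - z0), X, radii))
      ++cnt;
  }
  double f = (double)cnt / S;
  return 1.0 / (f / eps_in + (1.0 - f) / eps_out);
}

// [[Rcpp::export]]
List cpp_fdpb(NumericMatrix X, NumericVector q, NumericVector radii, double h,
              double eps_in, double eps_out, double kappa, double padding,
              int max_iter, double tol, double fcoul) {
  const int natom = X.nrow();
  Grid g;
  g.h = h;
  double hi[3];
  for (int d = 0; d < 3; ++d) {
    double lo = R_PosInf, up = R_NegInf;
    for (int a = 0; a < natom; ++a) {
      lo = std::min(lo, X(a, d) - radii[a]);
      up = std::max(up, X(a, d) + radii[a]);
    }
    lo -= padding; up += padding;
    // align so the first atom sits on a grid node (best point-charge accuracy)
    lo = X(0, d) - h * std::ceil((X(0, d) - lo) / h);
    g.lo[d] = lo;
    hi[d] = up;
  }
  g.nx = (int)std::ceil((hi[0] - g.lo[0]) / h) + 1;
  g.ny = (int)std::ceil((hi[1] - g.lo[1]) / h) + 1;
  g.nz = (int)std::ceil((hi[2] - g.lo[2]) / h) + 1;
  const long N = (long)g.nx * g.ny * g.nz;

  std::vector<double> phi(N, 0.0), rho(N, 0.0), kap2(N, 0.0);
  std::vector<float> ex(N, 0.0f), ey(N, 0.0f), ez(N, 0.0f);

  // trilinear charge spreading (charges kept in e; source uses q directly)
  for (int a = 0; a < natom; ++a) {
    double u[3];
    int i0[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = (X(a, d) - g.lo[d]) / h;
      i0[d] = (int)std::floor(u[d]);
      u[d] -= i0[d];
      if (i0[d] < 0 || i0[d] + 1 >= (d == 0 ? g.nx : (d == 1 ? g.ny : g.nz)))
        stop("atom outside charge grid");
    }
    for (int dx = 0; dx < 2; ++dx)
      for (int dy = 0; dy < 2; ++dy)
        for (int dz = 0; dz < 2; ++dz) {
          double w = (dx ? u[0] : 1 - u[0]) * (dy ? u[1] : 1 - u[1]) *
                     (dz ? u[2] : 1 - u[2]);
          rho[g.id(i0[0] + dx, i0[1] + dy, i0[2] + dz)] += q[a] * w;
        }
  }

  // face dielectrics and node screening
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        double x = g.lo[0] + i * h, y = g.lo[1] + j * h, z = g.lo[2] + k * h;
        long c = g.id(i, j, k);
        if (i + 1 < g.nx)
          ex[c] = (float)face_eps(x, y, z, x + h, y, z, X, radii, eps_in, eps_out);
        if (j + 1 < g.ny)
          ey[c] = (float)face_eps(x, y, z, x, y + h, z, X, radii, eps_in, eps_out);
        if (k + 1 < g.nz)
          ez[c] = (float)face_eps(x, y, z, x, y, z + h, X, radii, eps_in, eps_out);
        if (kappa > 0.0)
          kap2[c] = inside_solute(x, y, z, X, radii) ? 0.0 : kappa * kappa;
      }

  // Dirichlet boundary: screened Coulomb in the solvent dielectric
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        if (i > 0 && i < g.nx - 1 && j > 0 && j < g.ny - 1 && k > 0 &&
            k < g.nz - 1)
          continue;
        double x = g.lo[0] + i * h, y = g.lo[1] + j * h, z = g.lo[2] + k * h;
        double v = 0.0;
        for (int a = 0; a < natom; ++a) {
          double dx = x - X(a, 0), dy = y - X(a, 1), dz = z - X(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 0.5 * h) r = 0.5 * h;
          v += fcoul * q[a] * std::exp(-kappa * r) / (eps_out * r);
        }
        phi[g.id(i, j, k)] = v;
      }

  const double fourpif = 4.0 * M_PI * fcoul;
  int nmax = std::max(g.nx, std::max(g.ny, g.nz));
  const double omega = 2.0 / (1.0 + M_PI / nmax);
  double resid = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    double maxdiff = 0.0, maxphi = 1e-30;
    for (int k = 1; k < g.nz - 1; ++k)
      for (int j = 1; j < g.ny - 1; ++j)
        for (int i = 1; i < g.nx - 1; ++i) {
          long c = g.id(i, j, k);
          double exm = ex[g.id(i - 1, j, k)], exp_ = ex[c];
          double eym = ey[g.id(i, j - 1, k)], eyp = ey[c];
          double ezm = ez[g.id(i, j, k - 1)], ezp = ez[c];
          double num = exm * phi[c - 1] + exp_ * phi[c + 1] +
                       eym * phi[c - g.nx] + eyp * phi[c + g.nx] +
                       ezm * phi[c - (long)g.nx * g.ny] +
                       ezp * phi[c + (long)g.nx * g.ny] + fourpif * rho[c] / h;
          double den = exm + exp_ + eym + eyp + ezm + ezp +
                       kap2[c] * eps_out * h * h;
          double upd = (1.0 - omega) * phi[c] + omega * num / den;
          double d = std::fabs(upd - phi[c]);
          if (d > maxdiff) maxdiff = d;
          phi[c] = upd;
          double ap = std::fabs(upd);
          if (ap > maxphi) maxphi = ap;
        }
    resid = maxdiff / maxphi;
    if (resid < tol) break;
  }

  double energy = 0.0;
  for (long c = 0; c < N; ++c)
    if (rho[c] != 0.0) energy += 0.5 * rho[c] * phi[c];

  return List::create(_["energy"] = energy, _["converged"] = (resid < tol),
                      _["residual"] = resid, _["iterations"] = iter + 1,
                      _["dims"] = IntegerVector::create(g.nx, g.ny, g.nz));
}
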