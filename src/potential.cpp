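#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

// Gaussian-kernel map deposition and its adjoint, plus restraint terms.
// Grids are column-major arrays of dim (nx, ny, nz); voxel (i,j,k) has world
// coordinate origin + (i,j,k) * vsize (origin = CENTER of voxel (0,0,0)).
// Kernels are truncated beyond cutoff_sigma * sigma and evaluated at voxel
// centers; the 1-D exponential factors are precomputed per atom so the inner
// loops are multiply-adds only. The kernel is shifted by its value at the
// cutoff (G(r) - G(cut) inside, 0 outside) so the deposited density is
// continuous in the atom position; the spatial gradient is unchanged by the
// constant shift, and the shift is ~exp(-cut^2/2) ~ 3e-4 of the peak.

static inline void axis_range(double xa, double cut, double o, double v,
                              int n, int &i0, int &i1) {
  i0 = (int)std::ceil((xa - cut - o) / v);
  i1 = (int)std::floor((xa + cut - o) / v);
  if (i0 < 0) i0 = 0;
  if (i1 > n - 1) i1 = n - 1;
}

// [[Rcpp::export]]
NumericVector cpp_deposit(NumericMatrix coords, NumericVector weights,
                          NumericVector origin, NumericVector vsize,
                          IntegerVector dims, double sigma,
                          double cutoff_sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double cut = cutoff_sigma * sigma;
  const double cut2 = cut * cut;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double shift = std::exp(-cut2 * inv2s2);
  std::vector<double> ex, ey, ez, dx, dy, dz;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    const double w = weights[a] * norm;
    int i0, i1, j0, j1, k0, k1;
    axis_range(xa, cut, origin[0], vsize[0], nx, i0, i1);
    axis_range(ya, cut, origin[1], vsize[1], ny, j0, j1);
    axis_range(za, cut, origin[2], vsize[2], nz, k0, k1);
    if (i1 < i0 || j1 < j0 || k1 < k0) continue;
    const int ni = i1 - i0 + 1, nj = j1 - j0 + 1, nk = k1 - k0 + 1;
    ex.resize(ni); ey.resize(nj); ez.resize(nk);
    dx.resize(ni); dy.resize(nj); dz.resize(nk);
    for (int i = 0; i < ni; ++i) {
      dx[i] = origin[0] + (i0 + i) * vsize[0] - xa;
      ex[i] = std::exp(-dx[i] * dx[i] * inv2s2);
    }
    for (int j = 0; j < nj; ++j) {
      dy[j] = origin[1] + (j0 + j) * vsize[1] - ya;
      ey[j] = std::exp(-dy[j] * dy[j] * inv2s2);
    }
    for (int k = 0; k < nk; ++k) {
      dz[k] = origin[2] + (k0 + k) * vsize[2] - za;
      ez[k] = std::exp(-dz[k] * dz[k] * inv2s2);
    }
    double *pout = REAL(out);
    for (int k = 0; k < nk; ++k) {
      const double z2 = dz[k] * dz[k];
      for (int j = 0; j < nj; ++j) {
        const double yz2 = z2 + dy[j] * dy[j];
        if (yz2 > cut2) continue;
        const double wyz = w * ey[j] * ez[k];
        const double wsh = w * shift;
        // analytic i-range of the sphere slice keeps the loop branch-free
        const double xmax = std::sqrt(cut2 - yz2);
        int is, ie;
        axis_range(xa, xmax, origin[0], vsize[0], nx, is, ie);
        if (ie < is) continue;
        double *row = pout + (R_xlen_t)nx * ((j0 + j) + (R_xlen_t)ny * (k0 + k));
        const double *exr = ex.data() - i0;
        for (int i = is; i <= ie; ++i) row[i] += wyz * exr[i] - wsh;
      }
    }
  }
  return out;
}

// Adjoint of cpp_deposit: given per-voxel coefficients g_i (= dE/dm_i^calc),
// returns the n x 3 matrix dE/dx_a = sum_i g_i * dm_i/dx_a with
// dm_i/dx_a = w * G(v_i - x_a) * (v_i - x_a) / sigma^2.
// [[Rcpp::export]]
NumericMatrix cpp_deposit_grad(NumericMatrix coords, NumericVector weights,
                               NumericVector origin, NumericVector vsize,
                               IntegerVector dims, double sigma,
                               double cutoff_sigma, NumericVector gcoef) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix grad(coords.nrow(), 3);
  const double cut = cutoff_sigma * sigma;
  const double cut2 = cut * cut;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double *pg = REAL(gcoef);
  std::vector<double> ex, ey, ez, dx, dy, dz;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double xa = coords(a, 0), ya = coords(a, 1), za = coords(a, 2);
    const double w = weights[a] * norm;
    int i0, i1, j0, j1, k0, k1;
    axis_range(xa, cut, origin[0], vsize[0], nx, i0, i1);
    axis_range(ya, cut, origin[1], vsize[1], ny, j0, j1);
    axis_range(za, cut, origin[2], vsize[2], nz, k0, k1);
    if (i1 < i0 || j1 < j0 || k1 < k0) continue;
    const int ni = i1 - i0 + 1, nj = j1 - j0 + 1, nk = k1 - k0 + 1;
    ex.resize(ni); ey.resize(nj); ez.resize(nk);
    dx.resize(ni); dy.resize(nj); dz.resize(nk);
    for (int i = 0; i < ni; ++i) {
      dx[i] = origin[0] + (i0 + i) * vsize[0] - xa;
      ex[i] = std::exp(-dx[i] * dx[i] * inv2s2);
    }
    for (int j = 0; j < nj; ++j) {
      dy[j] = origin[1] + (j0 + j) * vsize[1] - ya;
      ey[j] = std::exp(-dy[j] * dy[j] * inv2s2);
    }
    for (int k = 0; k < nk; ++k) {
      dz[k] = origin[2] + (k0 + k) * vsize[2] - za;
      ez[k] = std::exp(-dz[k] * dz[k] * inv2s2);
    }
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int k = 0; k < nk; ++k) {
      const double z2 = dz[k] * dz[k];
      for (int j = 0; j < nj; ++j) {
        const double yz2 = z2 + dy[j] * dy[j];
        if (yz2 > cut2) continue;
        const double wyz = w * ey[j] * ez[k];
        const double xmax = std::sqrt(cut2 - yz2);
        int is, ie;
        axis_range(xa, xmax, origin[0], vsize[0], nx, is, ie);
        if (ie < is) continue;
        const double *row = pg + (R_xlen_t)nx * ((j0 + j) + (R_xlen_t)ny * (k0 + k));
        const double *exr = ex.data() - i0;
        const double *dxr = dx.data() - i0;
        double s0 = 0.0, s1 = 0.0;  // sum g*G, sum g*G*dx
        for (int i = is; i <= ie; ++i) {
          const double t = row[i] * exr[i];
          s0 += t;
          s1 += t * dxr[i];
        }
        gx += wyz * s1;
        gy += wyz * s0 * dy[j];
        gz += wyz * s0 * dz[k];
      }
    }
    grad(a, 0) = gx * invs2;
    grad(a, 1) = gy * invs2;
    grad(a, 2) = gz * invs2;
  }
  return grad;
}

// Fused correlation pass: given the centered observed values and their
// population sigma, computes the calculated map's statistics, the Pearson
// C, and the per-voxel coefficient dE/dm_j^calc for energy kc * (1 - C):
// dE/dm_j = -(kc / (N so sc)) * [a_j - C (so/sc) (m_j - mbar_c)].
// Returns sc so the caller can diagnose a flat calculated map.
// [[Rcpp::export]]
List cpp_cc_coef(NumericVector a_centered, double so, NumericVector mc,
                 double kc) {
  const R_xlen_t N = mc.size();
  const double *a = REAL(a_centered);
  const double *m = REAL(mc);
  double s = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) s += m[i];
  const double mbar = s / N;
  double sc2 = 0.0, cov = 0.0;
  for (R_xlen_t i = 0; i < N; ++i) {
    const double b = m[i] - mbar;
    sc2 += b * b;
    cov += a[i] * b;
  }
  const double sc = std::sqrt(sc2 / N);
  if (!(sc > 0.0))
    return List::create(_["C"] = NA_REAL, _["sc"] = sc);
  const double C = cov / ((double)N * so * sc);
  NumericVector g(N);
  double *pg = REAL(g);
  const double f1 = -kc / ((double)N * so * sc);
  const double f2 = C * so / sc;
  for (R_xlen_t i = 0; i < N; ++i)
    pg[i] = f1 * (a[i] - f2 * (m[i] - mbar));
  return List::create(_["C"] = C, _["sc"] = sc, _["gcoef"] = g);
}

// Restraint energy and analytic gradient.
// bonds: harmonic k (d - d0)^2; angles: harmonic k (theta - theta0)^2
// (theta0 in radians); flat-bottom distances: 0 inside [lo, hi], harmonic
// outside; soft repulsion k_rep (r_rep - d)^2 for non-excluded pairs with
// d < r_rep (exclusions: bonded 1-2 pairs and angle 1-3 pairs).
// All index matrices are 0-based.
// [[Rcpp::export]]
List cpp_restraint_eg(NumericMatrix coords,
                      IntegerMatrix bond_ij, NumericVector bond_d0,
                      NumericVector bond_k,
                      IntegerMatrix ang_ijk, NumericVector ang_t0,
                      NumericVector ang_k,
                      IntegerMatrix dist_ij, NumericVector d_lo,
                      NumericVector d_hi, NumericVector dist_k,
                      double rep_r, double rep_k) {
  const int n = coords.nrow();
  NumericMatrix grad(n, 3);
  double energy = 0.0;
  double e_bond = 0.0, e_angle = 0.0, e_dist = 0.0, e_rep = 0.0;

  auto pair_term = [&](int i, int j, double dev, double k) {
    // dev = d - bound; adds k*dev^2 and gradient along the i->j axis
    double dxv = coords(j, 0) - coords(i, 0);
    double dyv = coords(j, 1) - coords(i, 1);
    double dzv = coords(j, 2) - coords(i, 2);
    double d = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
    if (d < 1e-12) d = 1e-12;
    const double f = 2.0 * k * dev / d;  // dE/dd * (unit vector scale)
    grad(i, 0) -= f * dxv; grad(i, 1) -= f * dyv; grad(i, 2) -= f * dzv;
    grad(j, 0) += f * dxv; grad(j, 1) += f * dyv; grad(j, 2) += f * dzv;
    return k * dev * dev;
  };

  auto dist_of = [&](int i, int j) {
    double dxv = coords(j, 0) - coords(i, 0);
    double dyv = coords(j, 1) - coords(i, 1);
    double dzv = coords(j, 2) - coords(i, 2);
    return std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
  };

  for (int b = 0; b < bond_ij.nrow(); ++b) {
    const int i = bond_ij(b, 0), j = bond_ij(b, 1);
    const double d = dist_of(i, j);
    e_bond += pair_term(i, j, d - bond_d0[b], bond_k[b]);
  }

  for (int r = 0; r < dist_ij.nrow(); ++r) {
    const int i = dist_ij(r, 0), j = dist_ij(r, 1);
    const double d = dist_of(i, j);
    if (d < d_lo[r])      e_dist += pair_term(i, j, d - d_lo[r], dist_k[r]);
    else if (d > d_hi[r]) e_dist += pair_term(i, j, d - d_hi[r], dist_k[r]);
  }

  for (int a = 0; a < ang_ijk.nrow(); ++a) {
    const int i = ang_ijk(a, 0), j = ang_ijk(a, 1), k = ang_ijk(a, 2);
    double ux = coords(i, 0) - coords(j, 0), uy = coords(i, 1) - coords(j, 1),
           uz = coords(i, 2) - coords(j, 2);
    double vx = coords(k, 0) - coords(j, 0), vy = coords(k, 1) - coords(j, 1),
           vz = coords(k, 2) - coords(j, 2);
    const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    const double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
    const double theta = std::acos(ct);
    const double st = std::sqrt(1.0 - ct * ct);
    const double dev = theta - ang_t0[a];
    e_angle += ang_k[a] * dev * dev;
    if (st < 1e-8) continue;  // gradient ill-defined at 0/pi; energy still counted
    const double pref = 2.0 * ang_k[a] * dev * (-1.0 / st);
    // d(cos theta)/d r_i = (v_hat - ct * u_hat) / nu ; symmetric for r_k
    const double uhx = ux / nu, uhy = uy / nu, uhz = uz / nu;
    const double vhx = vx / nv, vhy = vy / nv, vhz = vz / nv;
    const double gix = pref * (vhx - ct * uhx) / nu;
    const double giy = pref * (vhy - ct * uhy) / nu;
    const double giz = pref * (vhz - ct * uhz) / nu;
    const double gkx = pref * (uhx - ct * vhx) / nv;
    const double gky = pref * (uhy - ct * vhy) / nv;
    const double gkz = pref * (uhz - ct * vhz) / nv;
    grad(i, 0) += gix; grad(i, 1) += giy; grad(i, 2) += giz;
    grad(k, 0) += gkx; grad(k, 1) += gky; grad(k, 2) += gkz;
    grad(j, 0) -= gix + gkx; grad(j, 1) -= giy + gky; grad(j, 2) -= giz + gkz;
  }

  if (rep_k > 0.0 && rep_r > 0.0 && n > 1) {
    std::set<std::pair<int, int> > excl;
    auto add_excl = [&](int i, int j) {
      excl.insert(std::make_pair(std::min(i, j), std::max(i, j)));
    };
    for (int b = 0; b < bond_ij.nrow(); ++b) add_excl(bond_ij(b, 0), bond_ij(b, 1));
    // explicitly restrained pairs carry their own bounds
    for (int r = 0; r < dist_ij.nrow(); ++r) add_excl(dist_ij(r, 0), dist_ij(r, 1));
    for (int a = 0; a < ang_ijk.nrow(); ++a) {
      add_excl(ang_ijk(a, 0), ang_ijk(a, 1));
      add_excl(ang_ijk(a, 1), ang_ijk(a, 2));
      add_excl(ang_ijk(a, 0), ang_ijk(a, 2));
    }
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double d = dist_of(i, j);
        if (d >= rep_r) continue;
        if (excl.count(std::make_pair(i, j))) continue;
        e_rep += pair_term(i, j, d - rep_r, rep_k);
      }
    }
  }

  energy = e_bond + e_angle + e_dist + e_rep;
  return List::create(_["energy"] = energy, _["gradient"] = grad,
                      _["terms"] = NumericVector::create(
                          _["bond"] = e_bond, _["angle"] = e_angle,
                          _["distance"] = e_dist, _["repulsion"] = e_rep));
}
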