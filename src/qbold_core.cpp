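#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exterior dipole field of an infinitely long cylinder in a uniform field
// along +z:
//   delta_omega_i / omega0 = (Rc/r)^2 * cos(2*phi) * sin^2(theta)
// where r is the perpendicular distance to the axis, theta the axis/B0
// angle and phi the in-plane angle from the projection of B0.
// With a = perpendicular component of (p - origin) and e = unit projection
// of z onto the plane normal to the axis, this reduces to
//   kernel_i = C_i * (2*(a.e)^2 - r^2) / r^4,   C_i = Rc^2 * sin^2(theta).
//
// Cylinder data is held in structure-of-arrays form so the per-step loop
// over all vessels vectorises.
struct CylSet {
  int N;
  std::vector<double> ox, oy, oz, ux, uy, uz, ex, ey, ez, C;
};

static CylSet precompute_cyl(const NumericMatrix& cyl, double Rc) {
  CylSet g;
  g.N = cyl.nrow();
  for (auto* v : {&g.ox, &g.oy, &g.oz, &g.ux, &g.uy, &g.uz,
                  &g.ex, &g.ey, &g.ez, &g.C})
    v->resize(g.N);
  for (int i = 0; i < g.N; ++i) {
    g.ox[i] = cyl(i, 0); g.oy[i] = cyl(i, 1); g.oz[i] = cyl(i, 2);
    g.ux[i] = cyl(i, 3); g.uy[i] = cyl(i, 4); g.uz[i] = cyl(i, 5);
    double uz = g.uz[i];
    double sin2t = 1.0 - uz * uz;
    // projection of z onto the plane perpendicular to u: (0,0,1) - uz*u
    double px = -uz * g.ux[i], py = -uz * g.uy[i], pz = 1.0 - uz * uz;
    double pn = std::sqrt(px * px + py * py + pz * pz);
    if (pn < 1e-12 || sin2t < 1e-24) {
      // axis parallel to B0: the field term vanishes, e is arbitrary
      g.ex[i] = 1.0; g.ey[i] = 0.0; g.ez[i] = 0.0; g.C[i] = 0.0;
    } else {
      g.ex[i] = px / pn; g.ey[i] = py / pn; g.ez[i] = pz / pn;
      g.C[i] = Rc * Rc * sin2t;
    }
  }
  return g;
}

// scalar kernel + r^2 for one cylinder
static inline void eval_one(const CylSet& g, int i, double x, double y,
                            double z, double& r2, double& kernel) {
  double dx = x - g.ox[i], dy = y - g.oy[i], dz = z - g.oz[i];
  double t = dx * g.ux[i] + dy * g.uy[i] + dz * g.uz[i];
  double ax = dx - t * g.ux[i], ay = dy - t * g.uy[i], az = dz - t * g.uz[i];
  r2 = ax * ax + ay * ay + az * az;
  double ae = ax * g.ex[i] + ay * g.ey[i] + az * g.ez[i];
  kernel = (r2 > 0.0) ? g.C[i] * (2.0 * ae * ae - r2) / (r2 * r2) : 0.0;
}

// branch-free sweep over all cylinders at one position: fills r2buf and
// returns the kernel sum (0 if kernels == false)
static inline double sweep_all(const CylSet& g, double x, double y, double z,
                               double* r2buf, bool kernels) {
  const int N = g.N;
  const double* __restrict ox = g.ox.data();
  const double* __restrict oy = g.oy.data();
  const double* __restrict oz = g.oz.data();
  const double* __restrict ux = g.ux.data();
  const double* __restrict uy = g.uy.data();
  const double* __restrict uz = g.uz.data();
  const double* __restrict ex = g.ex.data();
  const double* __restrict ey = g.ey.data();
  const double* __restrict ez = g.ez.data();
  const double* __restrict C = g.C.data();
  double sum = 0.0;
  if (kernels) {
    for (int i = 0; i < N; ++i) {
      double dx = x - ox[i], dy = y - oy[i], dz = z - oz[i];
      double t = dx * ux[i] + dy * uy[i] + dz * uz[i];
      double ax = dx - t * ux[i], ay = dy - t * uy[i], az = dz - t * uz[i];
      double r2 = ax * ax + ay * ay + az * az;
      double ae = ax * ex[i] + ay * ey[i] + az * ez[i];
      r2buf[i] = r2;
      sum += C[i] * (2.0 * ae * ae - r2) / (r2 * r2);
    }
  } else {
    for (int i = 0; i < N; ++i) {
      double dx = x - ox[i], dy = y - oy[i], dz = z - oz[i];
      double t = dx * ux[i] + dy * uy[i] + dz * uz[i];
      double ax = dx - t * ux[i], ay = dy - t * uy[i], az = dz - t * uz[i];
      r2buf[i] = ax * ax + ay * ay + az * az;
    }
  }
  return sum;
}

//' Dimensionless field offset sum over all cylinders at given points
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_field_offset(NumericMatrix points, NumericMatrix cyl,
                               double Rc) {
  CylSet g = precompute_cyl(cyl, Rc);
  int M = points.nrow();
  NumericVector out(M);
  for (int m = 0; m < M; ++m) {
    double s = 0.0, r2, k;
    for (int i = 0; i < g.N; ++i) {
      eval_one(g, i, points(m, 0), points(m, 1), points(m, 2), r2, k);
      s += k;
    }
    out[m] = s;
  }
  return out;
}

//' Phase accrual (and vessel-entry detection) for one proton walk
//'
//' `pos` holds fine-resolution positions (row 1 = start). The field is
//' evaluated at the end of each coarse interval for every cylinder;
//' cylinders within the proximity threshold (`Rc^2/r^2 > prox` at either
//' coarse endpoint) have their contribution to that interval re-evaluated
//' on the fine grid, with the entry condition (r < Rc) checked at every
//' fine position. Distant cylinders are entry-checked at coarse endpoints
//' only (the fine-step RMS is far below Rc for all supported radii).
//' @noRd
// [[Rcpp::export]]
List cpp_walk_phase(NumericMatrix pos, NumericMatrix cyl, double Rc,
                    double omega0, double dt_fine, int nf, int nc, int nbins,
                    double prox, bool entry_only) {
  int n_coarse = nc * nbins;
  if (pos.nrow() != n_coarse * nf + 1)
    stop("position array does not match the step configuration");
  CylSet g = precompute_cyl(cyl, Rc);
  const int N = g.N;
  const double Rc2 = Rc * Rc;
  const double prox_r2 = Rc2 / prox;   // proximal iff r^2 < Rc^2/prox
  const double dt_coarse = dt_fine * nf;
  const double* px = &pos(0, 0);
  const double* py = &pos(0, 1);
  const double* pz = &pos(0, 2);

  NumericVector phase(nbins);
  std::vector<double> r2_prev(N), r2_now(N);

  // initial position: entry + proximity state
  sweep_all(g, px[0], py[0], pz[0], r2_prev.data(), false);
  for (int i = 0; i < N; ++i)
    if (r2_prev[i] < Rc2)
      return List::create(_["entered"] = true, _["entry_step"] = 0,
                          _["phase"] = phase);

  for (int j = 1; j <= n_coarse; ++j) {
    int row_end = j * nf;
    double x = px[row_end], y = py[row_end], z = pz[row_end];
    double sum = sweep_all(g, x, y, z, r2_now.data(), !entry_only);
    double minr2 = r2_now[0];
    for (int i = 1; i < N; ++i) minr2 = std::min(minr2, r2_now[i]);
    if (minr2 < Rc2)
      return List::create(_["entered"] = true, _["entry_step"] = row_end,
                          _["phase"] = phase);
    // proximity-flagged cylinders: replace the coarse-endpoint term by the
    // sum over the interval's fine positions
    double phi_fine = 0.0;
    for (int i = 0; i < N; ++i) {
      if (r2_now[i] < prox_r2 || r2_prev[i] < prox_r2) {
        double r2, k;
        if (!entry_only) {
          eval_one(g, i, x, y, z, r2, k);
          sum -= k;
        }
        for (int s = 1; s <= nf; ++s) {
          int row = (j - 1) * nf + s;
          eval_one(g, i, px[row], py[row], pz[row], r2, k);
          if (r2 < Rc2)
            return List::create(_["entered"] = true, _["entry_step"] = row,
                                _["phase"] = phase);
          phi_fine += k * dt_fine;
        }
      }
    }
    if (!entry_only) {
      int bin = (j - 1) / nc;
      phase[bin] += omega0 * (sum * dt_coarse + phi_fine);
    }
    std::swap(r2_prev, r2_now);
  }
  return List::create(_["entered"] = false, _["entry_step"] = -1,
                      _["phase"] = phase);
}
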