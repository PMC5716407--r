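#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear interpolation into a uniform table starting at 0 with spacing
// `step`; constant before the first knot, 0 beyond the last (the proton has
// out-ranged the curve).
static inline double tab_lookup(const double* tab, int n, double step, double x) {
  if (x <= 0.0) return tab[0];
  double u = x / step;
  int j = (int)u;
  if (j >= n - 1) return 0.0;
  double f = u - j;
  return tab[j] * (1.0 - f) + tab[j + 1] * f;
}

// Simplified Monte Carlo transport of one batch of protons.
//
// state: n x 7 matrix (x, y, z, dx, dy, dz, residual_range_mm); columns
// beyond the 7th are ignored.  curve_Z is the depth origin (nominal range)
// of the measured pristine curves: a proton with residual range r reads the
// curves at depth curve_Z - r, so SOBP range modulation (protons starting
// with reduced residual range) automatically realizes range-shifted copies
// of the measured curve.
// The phantom is a voxel raster of relative stopping power; deposits are
// scored on the (coarser) calculation grid.  Per geometric step `step`:
// water-equivalent loss dwed = rsp * step, curve lookup scaled by dwed,
// Highland multiple-scattering kick per projection.  Uses R's RNG (set the
// seed in R).
//
// dose_acc / out_acc are accumulated in place (column-major calc-grid
// order); the function returns the number of protons that stopped inside
// the phantom.
// [[Rcpp::export]]
int smc_transport_batch(NumericMatrix state,
                        NumericVector rsp, IntegerVector ph_shape,
                        NumericVector ph_vs, NumericVector ph_origin,
                        IntegerVector cg_shape, NumericVector cg_vs,
                        NumericVector cg_origin,
                        NumericVector dd_tab, NumericVector do_tab,
                        double tab_step, double curve_Z,
                        NumericVector pv_tab, double pv_step,
                        double step, double x0_water,
                        NumericVector dose_acc, NumericVector out_acc) {
  const int n = state.nrow();
  const int pnx = ph_shape[0], pny = ph_shape[1], pnz = ph_shape[2];
  const int cnx = cg_shape[0], cny = cg_shape[1], cnz = cg_shape[2];
  const double* ddp = REAL(dd_tab); const int ndd = dd_tab.size();
  const double* dop = REAL(do_tab); const int ndo = do_tab.size();
  const double* pvp = REAL(pv_tab); const int npv = pv_tab.size();
  const double* rp = REAL(rsp);
  double* dacc = REAL(dose_acc);
  double* oacc = REAL(out_acc);
  RNGScope scope;
  int n_stopped = 0;

  for (int i = 0; i < n; ++i) {
    double x = state(i, 0), y = state(i, 1), z = state(i, 2);
    double dx = state(i, 3), dy = state(i, 4), dz = state(i, 5);
    double resid = state(i, 6);
    for (;;) {
      if (resid <= 1e-9) { ++n_stopped; break; }
      // midpoint of the step locates both the material and the score voxel
      double mx = x + dx * step * 0.5;
      double my = y + dy * step * 0.5;
      double mz = z + dz * step * 0.5;
      int ix = (int)std::floor((mx - ph_origin[0]) / ph_vs[0] + 0.5);
      int iy = (int)std::floor((my - ph_origin[1]) / ph_vs[1] + 0.5);
      int iz = (int)std::floor((mz - ph_origin[2]) / ph_vs[2] + 0.5);
      if (ix < 0 || ix >= pnx || iy < 0 || iy >= pny || iz < 0 || iz >= pnz)
        break;  // proton exits the phantom: dropped
      double rv = rp[ix + (R_xlen_t)pnx * (iy + (R_xlen_t)pny * iz)];
      double step_geom = step;
      double dwed = rv * step;
      if (dwed >= resid) {          // final partial step: stop exactly at r = 0
        step_geom = (rv > 0.0) ? step * resid / dwed : step;
        dwed = resid;
      }
      if (dwed > 0.0) {
        double r_mid = resid - 0.5 * dwed;
        double depth = curve_Z - r_mid;
        double vd = tab_lookup(ddp, ndd, tab_step, depth);
        double vo = tab_lookup(dop, ndo, tab_step, depth);
        int jx = (int)std::floor((mx - cg_origin[0]) / cg_vs[0] + 0.5);
        int jy = (int)std::floor((my - cg_origin[1]) / cg_vs[1] + 0.5);
        int jz = (int)std::floor((mz - cg_origin[2]) / cg_vs[2] + 0.5);
        if (jx >= 0 && jx < cnx && jy >= 0 && jy < cny && jz >= 0 && jz < cnz) {
          R_xlen_t j = jx + (R_xlen_t)cnx * (jy + (R_xlen_t)cny * jz);
          dacc[j] += vd * dwed;
          oacc[j] += vo * dwed;
        }
      }
      x += dx * step_geom; y += dy * step_geom; z += dz * step_geom;
      resid -= dwed;
      if (resid <= 1e-9) { ++n_stopped; break; }
      // Highland multiple Coulomb scattering for the step just taken
      if (rv > 1e-6) {
        double lo = step_geom * rv / x0_water;  // radiation lengths traversed
        double pv = tab_lookup(pvp, npv, pv_step, resid);
        if (pv < 1.0) pv = 1.0;
        double th0 = 14.1 / pv * std::sqrt(lo) *
                     (1.0 + std::log10(lo) / 9.0);
        if (th0 > 0.0) {
          double tx = norm_rand() * th0;
          double ty = norm_rand() * th0;
          // orthonormal frame (e1, e2) perpendicular to the direction
          double ax = 0.0, ay = 0.0, az = 1.0;
          if (std::fabs(dz) > 0.9) { ax = 1.0; az = 0.0; }
          double e1x = dy * az - dz * ay;
          double e1y = dz * ax - dx * az;
          double e1z = dx * ay - dy * ax;
          double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
          e1x /= n1; e1y /= n1; e1z /= n1;
          double e2x = dy * e1z - dz * e1y;
          double e2y = dz * e1x - dx * e1z;
          double e2z = dx * e1y - dy * e1x;
          dx += tx * e1x + ty * e2x;
          dy += tx * e1y + ty * e2y;
          dz += tx * e1z + ty * e2z;
          double nn = std::sqrt(dx * dx + dy * dy + dz * dz);
          dx /= nn; dy /= nn; dz /= nn;
        }
      }
    }
  }
  return n_stopped;
}
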