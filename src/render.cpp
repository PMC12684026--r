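#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Renders the two-component bead image model onto the sheared acquisition
// grid of one view. Stack voxel (n, r, c) [0-based] maps to world
//   x = c * px
//   y = sweep * n * step + s * r * px * cos(tau)
//   z = r * px * sin(tau)
// with s = +1 (view 1) or -1 (view 2), sweep = +1 (remote) or -1 (stage).
// The bead image in world offsets (dx, dy, dz) about a bead at depth zb is
//   A/a * [ exp(-dx^2/2sx^2 - dy^2/2sy^2 - dz^2/2(a sz)^2)
//           + (sx*sy/sh^2) * exp(-(dx^2+dy^2)/2sh^2)
//             * ( kappa * exp(-dz^2/2(a st)^2) - exp(-dz^2/2(a sz)^2) ) ]
// where a = 1 + mismatch * |zb - focus| broadens the axial widths and the
// 1/a prefactor conserves the integrated signal.
// [[Rcpp::export(name = ".renderBeads")]]
NumericVector renderBeads(NumericVector vox, IntegerVector dims,
                          NumericMatrix pos, NumericVector amp,
                          double px, double step, double tilt_deg,
                          int view_sign, int sweep_sign,
                          double sx, double sy, double sz,
                          double sh, double st, double kappa,
                          double mismatch, double focus_depth,
                          double support_sigmas) {
  const int N = dims[0], R = dims[1], C = dims[2];
  const double tau = tilt_deg * M_PI / 180.0;
  const double ct = std::cos(tau), stt = std::sin(tau);
  const double s = (double)view_sign, sw = (double)sweep_sign;
  const double halo_pref = (sx * sy) / (sh * sh);
  double* v = REAL(vox);

  for (int b = 0; b < pos.nrow(); ++b) {
    const double bx = pos(b, 0), by = pos(b, 1), bz = pos(b, 2);
    const double A = amp[b];
    const double a = 1.0 + mismatch * std::fabs(bz - focus_depth);
    const double szz = a * sz, stz = a * st;
    // world-space support radii
    const double Rlat = support_sigmas * std::max(sy, sh);
    const double Rx   = support_sigmas * std::max(sx, sh);
    const double Rax  = support_sigmas * std::max(stz, szz);
    // index bounds: c from x, r from z, n from y and z
    int c0 = (int)std::floor((bx - Rx) / px), c1 = (int)std::ceil((bx + Rx) / px);
    int r0 = (int)std::floor((bz - Rax) / (px * stt));
    int r1 = (int)std::ceil((bz + Rax) / (px * stt));
    if (c0 < 0) c0 = 0; if (c1 > C - 1) c1 = C - 1;
    if (r0 < 0) r0 = 0; if (r1 > R - 1) r1 = R - 1;
    if (c0 > c1 || r0 > r1) continue;
    const double inv2sx = 1.0 / (2.0 * sx * sx);
    const double inv2sy = 1.0 / (2.0 * sy * sy);
    const double inv2sz = 1.0 / (2.0 * szz * szz);
    const double inv2sh = 1.0 / (2.0 * sh * sh);
    const double inv2st = 1.0 / (2.0 * stz * stz);
    for (int r = r0; r <= r1; ++r) {
      const double z = r * px * stt;
      const double dz = z - bz;
      const double gz = std::exp(-dz * dz * inv2sz);
      const double ax = kappa * std::exp(-dz * dz * inv2st) - gz;
      // frames where |y - by| <= Rlat: y = sw*n*step + s*r*px*ct
      const double yr = s * r * px * ct;
      double nlo = (by - Rlat - yr) / (sw * step);
      double nhi = (by + Rlat - yr) / (sw * step);
      if (nlo > nhi) std::swap(nlo, nhi);
      int n0 = (int)std::floor(nlo), n1 = (int)std::ceil(nhi);
      if (n0 < 0) n0 = 0; if (n1 > N - 1) n1 = N - 1;
      for (int n = n0; n <= n1; ++n) {
        const double y = sw * n * step + yr;
        const double dy = y - by;
        const double gy = std::exp(-dy * dy * inv2sy);
        const double hy = std::exp(-dy * dy * inv2sh);
        for (int c = c0; c <= c1; ++c) {
          const double dx = c * px - bx;
          const double gx = std::exp(-dx * dx * inv2sx);
          const double hx = std::exp(-dx * dx * inv2sh);
          const double val = (A / a) * (gx * gy * gz + halo_pref * hx * hy * ax);
          v[(R_xlen_t)n + (R_xlen_t)N * r + (R_xlen_t)N * R * c] += val;
        }
      }
    }
  }
  return vox;
}

// Adds a uniform background, Poisson shot noise and Gaussian read noise in
// place, clamping at 0. Uses R's RNG so results are reproducible under
// set.seed().
// [[Rcpp::export(name = ".addCameraNoise")]]
NumericVector addCameraNoise(NumericVector vox, double background,
                             double read_sd) {
  RNGScope scope;
  double* v = REAL(vox);
  const R_xlen_t n = vox.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double lam = v[i] + background;
    double x = (lam > 0) ? R::rpois(lam) : 0.0;
    if (read_sd > 0) x += R::rnorm(0.0, read_sd);
    v[i] = (x > 0) ? x : 0.0;
  }
  return vox;
}
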