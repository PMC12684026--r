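#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared geometry: output voxel (i0, i1, i2) of an array [d0, d1, d2]
// (column-major, [z, y, x] for volumes) has world position
//   x = ox + i2 * vx,  y = oy + i1 * vy,  z = oz + i0 * vz
// and maps to fractional source index f = M * (x, y, z) + t, where f indexes
// the source array in its own storage order.

static inline double clampi(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline void cr_weights(double t, double* w) {
  // Catmull-Rom cubic interpolation weights for offsets -1, 0, 1, 2
  const double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// [[Rcpp::export(name = ".affineResample")]]
List affineResample(NumericVector src, IntegerVector sdims,
                    NumericMatrix M, NumericVector tr,
                    IntegerVector odims, NumericVector ovoxel,
                    NumericVector oorigin, int method, double fill) {
  const int S0 = sdims[0], S1 = sdims[1], S2 = sdims[2];
  const int D0 = odims[0], D1 = odims[1], D2 = odims[2];
  const double* sv = REAL(src);
  NumericVector out((R_xlen_t)D0 * D1 * D2, fill);
  LogicalVector valid((R_xlen_t)D0 * D1 * D2, FALSE);
  double* ov = REAL(out);
  int* va = LOGICAL(valid);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);

  R_xlen_t idx = 0;
  for (int i2 = 0; i2 < D2; ++i2) {
    const double x = oorigin[0] + i2 * ovoxel[0];
    for (int i1 = 0; i1 < D1; ++i1) {
      const double y = oorigin[1] + i1 * ovoxel[1];
      for (int i0 = 0; i0 < D0; ++i0, ++idx) {
        const double z = oorigin[2] + i0 * ovoxel[2];
        const double f0 = m00 * x + m01 * y + m02 * z + tr[0];
        const double f1 = m10 * x + m11 * y + m12 * z + tr[1];
        const double f2 = m20 * x + m21 * y + m22 * z + tr[2];
        if (f0 < 0 || f0 > S0 - 1 || f1 < 0 || f1 > S1 - 1 ||
            f2 < 0 || f2 > S2 - 1)
          continue;
        va[idx] = TRUE;
        if (method == 0) {                      // trilinear
          int a0 = (int)std::floor(f0), a1 = (int)std::floor(f1),
              a2 = (int)std::floor(f2);
          if (a0 > S0 - 2) a0 = S0 - 2; if (a0 < 0) a0 = 0;
          if (a1 > S1 - 2) a1 = S1 - 2; if (a1 < 0) a1 = 0;
          if (a2 > S2 - 2) a2 = S2 - 2; if (a2 < 0) a2 = 0;
          const double u0 = f0 - a0, u1 = f1 - a1, u2 = f2 - a2;
          double acc = 0.0;
          for (int k2 = 0; k2 <= 1; ++k2) {
            const double w2 = k2 ? u2 : 1.0 - u2;
            for (int k1 = 0; k1 <= 1; ++k1) {
              const double w12 = w2 * (k1 ? u1 : 1.0 - u1);
              for (int k0 = 0; k0 <= 1; ++k0) {
                const double w = w12 * (k0 ? u0 : 1.0 - u0);
                acc += w * sv[(R_xlen_t)(a0 + k0) +
                              (R_xlen_t)S0 * (a1 + k1) +
                              (R_xlen_t)S0 * S1 * (a2 + k2)];
              }
            }
          }
          ov[idx] = acc;
        } else {                                // Catmull-Rom cubic
          const int a0 = (int)std::floor(f0), a1 = (int)std::floor(f1),
                    a2 = (int)std::floor(f2);
          double w0[4], w1[4], w2[4];
          cr_weights(f0 - a0, w0);
          cr_weights(f1 - a1, w1);
          cr_weights(f2 - a2, w2);
          double acc = 0.0;
          for (int k2 = 0; k2 < 4; ++k2) {
            const int j2 = (int)clampi(a2 - 1 + k2, 0, S2 - 1);
            for (int k1 = 0; k1 < 4; ++k1) {
              const int j1 = (int)clampi(a1 - 1 + k1, 0, S1 - 1);
              const double w12 = w2[k2] * w1[k1];
              if (w12 == 0.0) continue;
              for (int k0 = 0; k0 < 4; ++k0) {
                const int j0 = (int)clampi(a0 - 1 + k0, 0, S0 - 1);
                acc += w12 * w0[k0] *
                       sv[(R_xlen_t)j0 + (R_xlen_t)S0 * j1 +
                          (R_xlen_t)S0 * S1 * j2];
              }
            }
          }
          ov[idx] = acc;
        }
      }
    }
  }
  out.attr("dim") = odims;
  valid.attr("dim") = odims;
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Conservative mask transport: an output voxel is valid only if it maps
// inside the source and all 8 surrounding source mask voxels are valid.
// [[Rcpp::export(name = ".affineResampleMask")]]
LogicalVector affineResampleMask(LogicalVector mask, IntegerVector sdims,
                                 NumericMatrix M, NumericVector tr,
                                 IntegerVector odims, NumericVector ovoxel,
                                 NumericVector oorigin) {
  const int S0 = sdims[0], S1 = sdims[1], S2 = sdims[2];
  const int D0 = odims[0], D1 = odims[1], D2 = odims[2];
  const int* mv = LOGICAL(mask);
  LogicalVector out((R_xlen_t)D0 * D1 * D2, FALSE);
  int* ov = LOGICAL(out);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  R_xlen_t idx = 0;
  for (int i2 = 0; i2 < D2; ++i2) {
    const double x = oorigin[0] + i2 * ovoxel[0];
    for (int i1 = 0; i1 < D1; ++i1) {
      const double y = oorigin[1] + i1 * ovoxel[1];
      for (int i0 = 0; i0 < D0; ++i0, ++idx) {
        const double z = oorigin[2] + i0 * ovoxel[2];
        const double f0 = m00 * x + m01 * y + m02 * z + tr[0];
        const double f1 = m10 * x + m11 * y + m12 * z + tr[1];
        const double f2 = m20 * x + m21 * y + m22 * z + tr[2];
        if (f0 < 0 || f0 > S0 - 1 || f1 < 0 || f1 > S1 - 1 ||
            f2 < 0 || f2 > S2 - 1)
          continue;
        int a0 = (int)std::floor(f0), a1 = (int)std::floor(f1),
            a2 = (int)std::floor(f2);
        if (a0 > S0 - 2) a0 = S0 - 2; if (a0 < 0) a0 = 0;
        if (a1 > S1 - 2) a1 = S1 - 2; if (a1 < 0) a1 = 0;
        if (a2 > S2 - 2) a2 = S2 - 2; if (a2 < 0) a2 = 0;
        bool ok = true;
        for (int k2 = 0; k2 <= 1 && ok; ++k2)
          for (int k1 = 0; k1 <= 1 && ok; ++k1)
            for (int k0 = 0; k0 <= 1 && ok; ++k0)
              if (!mv[(R_xlen_t)(a0 + k0) + (R_xlen_t)S0 * (a1 + k1) +
                      (R_xlen_t)S0 * S1 * (a2 + k2)])
                ok = false;
        ov[idx] = ok;
      }
    }
  }
  out.attr("dim") = odims;
  return out;
}
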