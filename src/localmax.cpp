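#include <Rcpp.h>
using namespace Rcpp;

// 26-neighbourhood local maxima of a 3D array above a threshold, restricted
// to a validity mask. Plateau ties are broken towards the lowest linear
// index so each flat-topped peak yields exactly one candidate. Returns
// 0-based (i0, i1, i2) indices.
// [[Rcpp::export(name = ".localMaxima3d")]]
IntegerMatrix localMaxima3d(NumericVector vol, IntegerVector dims,
                            Nullable<LogicalVector> mask_, double threshold) {
  const int D0 = dims[0], D1 = dims[1], D2 = dims[2];
  const double* v = REAL(vol);
  const int* m = NULL;
  if (mask_.isNotNull()) {
    LogicalVector mm(mask_);
    m = LOGICAL(mm);
  }
  std::vector<int> out;
  for (int i2 = 1; i2 < D2 - 1; ++i2)
    for (int i1 = 1; i1 < D1 - 1; ++i1)
      for (int i0 = 1; i0 < D0 - 1; ++i0) {
        const R_xlen_t idx = (R_xlen_t)i0 + (R_xlen_t)D0 * i1 +
                             (R_xlen_t)D0 * D1 * i2;
        if (m && !m[idx]) continue;
        const double val = v[idx];
        if (val <= threshold) continue;
        bool is_max = true;
        for (int k2 = -1; k2 <= 1 && is_max; ++k2)
          for (int k1 = -1; k1 <= 1 && is_max; ++k1)
            for (int k0 = -1; k0 <= 1 && is_max; ++k0) {
              if (!k0 && !k1 && !k2) continue;
              const R_xlen_t j = idx + k0 + (R_xlen_t)D0 * k1 +
                                 (R_xlen_t)D0 * D1 * k2;
              if (v[j] > val || (v[j] == val && j < idx)) is_max = false;
            }
        if (is_max) {
          out.push_back(i0); out.push_back(i1); out.push_back(i2);
        }
      }
  const int n = (int)(out.size() / 3);
  IntegerMatrix res(n, 3);
  for (int i = 0; i < n; ++i) {
    res(i, 0) = out[3 * i];
    res(i, 1) = out[3 * i + 1];
    res(i, 2) = out[3 * i + 2];
  }
  return res;
}
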