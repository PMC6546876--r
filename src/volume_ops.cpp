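#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian filter on a 3D volume. sigma_vox is per-axis in voxel
// units; kernel truncated at 4 sigma and normalized. boundary: 0 = reflect
// (edge mirrored, scipy-style: index -1 maps to 0), 1 = constant zero.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim3,
                                  NumericVector sigma_vox, int boundary) {
  const int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> cur(vol.begin(), vol.begin() + nvox), nxt(nvox);
  const int dims[3] = {nx, ny, nz};
  const size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 0) continue;
    const int r = (int)(4.0 * s + 0.5);
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      w[k + r] = std::exp(-0.5 * (k / s) * (k / s));
      tot += w[k + r];
    }
    for (double &x : w) x /= tot;

    const int nax = dims[ax];
    const size_t st = strides[ax];
    // iterate over all lines along axis ax
    const int d1 = (ax == 0) ? 1 : 0;
    const int d2 = (ax == 2) ? 1 : 2;
    for (int j = 0; j < dims[d2]; ++j)
      for (int i = 0; i < dims[d1]; ++i) {
        const size_t base = strides[d1] * i + strides[d2] * j;
        for (int p = 0; p < nax; ++p) {
          double acc = 0.0;
          for (int k = -r; k <= r; ++k) {
            int q = p + k;
            if (q < 0 || q >= nax) {
              if (boundary == 1) continue; // zero outside
              // reflect about the edge: ... c b a | a b c ...
              while (q < 0 || q >= nax) {
                if (q < 0) q = -q - 1;
                if (q >= nax) q = 2 * nax - 1 - q;
              }
            }
            acc += w[k + r] * cur[base + st * q];
          }
          nxt[base + st * p] = acc;
        }
      }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Connected-component labeling of a boolean 3D volume. connectivity 6 (faces),
// 18 (faces + edges) or 26 (full cube). Components labeled 1..L in raster
// scan order of their first-encountered voxel; background = 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector flag, IntegerVector dim3,
                                   int connectivity) {
  const int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<int> nb; // neighbor offsets as packed (dx,dy,dz)
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (man == 0) continue;
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        nb.push_back(dx);
        nb.push_back(dy);
        nb.push_back(dz);
      }
  IntegerVector lab(nvox, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t seed = 0; seed < nvox; ++seed) {
    if (!flag[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.assign(1, seed);
    while (!stack.empty()) {
      const size_t c = stack.back();
      stack.pop_back();
      const int x = (int)(c % nx), y = (int)((c / nx) % ny),
                z = (int)(c / ((size_t)nx * ny));
      for (size_t k = 0; k < nb.size(); k += 3) {
        const int ox = x + nb[k], oy = y + nb[k + 1], oz = z + nb[k + 2];
        if (ox < 0 || oy < 0 || oz < 0 || ox >= nx || oy >= ny || oz >= nz)
          continue;
        const size_t q = (size_t)ox + (size_t)nx * (oy + (size_t)ny * oz);
        if (flag[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
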