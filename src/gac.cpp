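#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Morphological geodesic-active-contour iteration on a binary level set u:
// advection of the front along the gradient of the edge-stopping image g
// (precomputed central-difference gradients dgx, dgy), followed by a
// 3x3 binary majority filter approximating curvature flow.
// [[Rcpp::export]]
IntegerMatrix cpp_morph_gac(NumericMatrix dgx, NumericMatrix dgy,
                            IntegerMatrix mask, int iterations) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> u(H * W), nu(H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) u[j * H + i] = mask(i, j) ? 1 : 0;
  for (int it = 0; it < iterations; ++it) {
    // advection step: du/dt = grad(g) . grad(u)
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int idx = j * H + i;
        int ip = (i + 1 < H) ? i + 1 : i, im = (i > 0) ? i - 1 : i;
        int jp = (j + 1 < W) ? j + 1 : j, jm = (j > 0) ? j - 1 : j;
        double duy = 0.5 * (u[j * H + ip] - u[j * H + im]);
        double dux = 0.5 * (u[jp * H + i] - u[jm * H + i]);
        double adv = dgx(i, j) * dux + dgy(i, j) * duy;
        int v = u[idx];
        if (adv > 1e-8) v = 1;
        else if (adv < -1e-8) v = 0;
        nu[idx] = v;
      }
    }
    std::swap(u, nu);
    // curvature smoothing: 3x3 majority
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        int s = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0) jj = 0; if (jj >= W) jj = W - 1;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0) ii = 0; if (ii >= H) ii = H - 1;
            s += u[jj * H + ii];
          }
        }
        nu[j * H + i] = (s > 4) ? 1 : 0;
      }
    }
    std::swap(u, nu);
  }
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = u[j * H + i];
  return out;
}
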