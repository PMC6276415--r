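#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Best CART split over all observed values of all features for the samples
// in idx (1-based rows of x).  Gain is the weighted-SSE reduction
// SSE_T - SSE_L - SSE_R of the 2-D displacement targets; routing is
// "strictly less goes left" with the threshold at the observed value.
// Ties keep the lowest feature index, then the smallest threshold.
// Returns (feature, threshold, gain); feature = 0 when no candidate has
// positive gain.
// [[Rcpp::export]]
NumericVector cpp_best_split(const NumericMatrix& x, const NumericVector& dx,
                             const NumericVector& dy, const NumericVector& w,
                             const IntegerVector& idx) {
  const int n = idx.size(), F = x.ncol();
  if (n < 2) return NumericVector::create(0, 0, 0);
  std::vector<double> wi(n), wdx(n), wdy(n), wd2(n);
  double P = 0, sx = 0, sy = 0, s2 = 0;
  for (int i = 0; i < n; i++) {
    const int j = idx[i] - 1;
    const double a = dx[j], b = dy[j];
    wi[i] = w[j];
    wdx[i] = wi[i] * a; wdy[i] = wi[i] * b; wd2[i] = wi[i] * (a * a + b * b);
    P += wi[i]; sx += wdx[i]; sy += wdy[i]; s2 += wd2[i];
  }
  const double sse_t = s2 - (sx * sx + sy * sy) / P;
  double best_gain = 0, best_thr = 0;
  int best_f = 0;
  std::vector<int> ord(n);
  std::vector<double> xf(n);
  for (int f = 0; f < F; f++) {
    for (int i = 0; i < n; i++) xf[i] = x(idx[i] - 1, f);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return xf[a] < xf[b]; });
    double cw = 0, cx = 0, cy = 0, c2 = 0;
    for (int i = 0; i < n - 1; i++) {
      const int o = ord[i];
      cw += wi[o]; cx += wdx[o]; cy += wdy[o]; c2 += wd2[o];
      const double xnext = xf[ord[i + 1]];
      if (xnext > xf[o]) {
        const double sse_l = c2 - (cx * cx + cy * cy) / cw;
        const double rx = sx - cx, ry = sy - cy;
        const double sse_r = (s2 - c2) - (rx * rx + ry * ry) / (P - cw);
        const double gain = sse_t - sse_l - sse_r;
        if (gain > best_gain) {
          best_gain = gain; best_f = f + 1; best_thr = xnext;
        }
      }
    }
  }
  return NumericVector::create(best_f, best_thr, best_gain);
}

// SIFT-style 128-long patch descriptors at integer centers (0-based x, y).
// Patch side 2W+1, edge replication at the image border; per-patch central
// differences with replicated patch borders; hard orientation binning of
// gradient magnitude into a 4x4 grid of 8-bin histograms, concatenated
// row-major.  Mirrors the definitions of patch_gradient() and the cell
// partition floor(side * i / 4).
// [[Rcpp::export]]
NumericMatrix cpp_sift_descriptors(const NumericMatrix& px,
                                   const IntegerVector& cx,
                                   const IntegerVector& cy, const int W) {
  const int h = px.nrow(), w = px.ncol(), n = cx.size();
  const int side = 2 * W + 1;
  std::vector<int> cell1d(side);
  {
    int bnd[5];
    for (int i = 0; i <= 4; i++) bnd[i] = (int)std::floor(side * i / 4.0);
    for (int r = 0; r < side; r++) {
      int c = 0;
      while (c < 3 && r >= bnd[c + 1]) c++;
      cell1d[r] = c;
    }
  }
  const double k = 8.0 / (2.0 * M_PI);
  NumericMatrix out(n, 128);
  std::vector<double> patch(side * side);
  double acc[128];
  for (int p = 0; p < n; p++) {
    for (int c = 0; c < side; c++) {
      int xc = cx[p] - W + c;
      xc = std::min(std::max(xc, 0), w - 1);
      const double* col = &px(0, xc);
      for (int r = 0; r < side; r++) {
        int yr = cy[p] - W + r;
        yr = std::min(std::max(yr, 0), h - 1);
        patch[c * side + r] = col[yr];
      }
    }
    std::fill(acc, acc + 128, 0.0);
    for (int c = 0; c < side; c++) {
      const int cl = std::max(c - 1, 0), cr = std::min(c + 1, side - 1);
      for (int r = 0; r < side; r++) {
        const int ru = std::max(r - 1, 0), rd = std::min(r + 1, side - 1);
        const double gx = (patch[cr * side + r] - patch[cl * side + r]) / 2.0;
        const double gy = (patch[c * side + rd] - patch[c * side + ru]) / 2.0;
        const double gm = std::sqrt(gx * gx + gy * gy);
        double ga = (gm == 0.0) ? 0.0 : std::atan2(gy, gx);
        if (ga < 0) ga += 2.0 * M_PI;
        int bin = (int)std::floor(ga * k);
        if (bin > 7) bin = 7;
        acc[(cell1d[r] * 4 + cell1d[c]) * 8 + bin] += gm;
      }
    }
    for (int j = 0; j < 128; j++) out(p, j) = acc[j];
  }
  return out;
}
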