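#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Local Shannon entropy over a disk neighbourhood with reflect padding.
//
// Intensities are clamped to [0, 1] and quantised into `bins` equal-width
// levels over that fixed range; the per-pixel value is the entropy (in bits)
// of the level histogram of the disk of radius `radius` centred on the pixel.
// The level grid is offset by half a bin so that mid-gray (0.5, the zero of
// the flat-field correction) falls in a bin interior: otherwise vanishing
// residuals in flat regions would straddle a bin edge and read as texture.
// Reflect indexing mirrors without repeating the border pixel (like
// "symmetric" padding), which keeps the filter free of frame-edge darkening.

static inline int reflect_index(int i, int n) {
  // maps any integer onto [0, n) by mirroring at the boundaries
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export(name = ".entropy_disk_cpp")]]
NumericMatrix entropy_disk_cpp(NumericMatrix img, int radius, int bins) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);

  // precompute disk offsets
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  const int K = (int)dr.size();
  const double dK = (double)K;   // divide, not multiply: hist == K gives p == 1 exactly

  // quantise once
  std::vector<int> q((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (v < 0) v = 0; else if (v > 1) v = 1;
      int b = (int)std::floor(v * bins + 0.5);
      if (b >= bins) b = bins - 1;
      q[(size_t)j * nr + i] = b;
    }

  std::vector<int> hist(bins);
  const double log2inv = 1.0 / std::log(2.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int k = 0; k < K; ++k) {
        int ri = reflect_index(i + dr[k], nr);
        int cj = reflect_index(j + dc[k], nc);
        ++hist[q[(size_t)cj * nr + ri]];
      }
      double H = 0.0;
      for (int b = 0; b < bins; ++b) {
        if (hist[b] > 0) {
          double p = hist[b] / dK;
          H -= p * std::log(p) * log2inv;
        }
      }
      out(i, j) = H;
    }
  }
  return out;
}
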