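#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Mirror index into [0, n) with symmetric (half-sample) reflection:
// -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2. Matches symmetric padding.
static inline int reflect_sym(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline int clamp_idx(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// Per-pixel Shannon entropy (bits) of the histogram of a (window x window)
// neighborhood, values pre-binned into `bins` equal-width bins over
// [0, 65535]; symmetric boundary padding.
// [[Rcpp::export]]
NumericMatrix entropy_filter_cpp(IntegerMatrix img, int window, int bins) {
  const int h = img.nrow(), w = img.ncol();
  const int r = window / 2;
  const int div = 65536 / bins;
  NumericMatrix out(h, w);
  std::vector<int> hist(bins);
  const double n = (double)window * window;
  const double log2inv = 1.0 / std::log(2.0);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int di = -r; di <= r; ++di) {
        const int ii = reflect_sym(i + di, h);
        for (int dj = -r; dj <= r; ++dj) {
          const int jj = reflect_sym(j + dj, w);
          hist[img(ii, jj) / div]++;
        }
      }
      double ent = 0.0;
      for (int b = 0; b < bins; ++b) {
        if (hist[b] > 0) {
          const double p = hist[b] / n;
          ent -= p * std::log(p) * log2inv;
        }
      }
      out(i, j) = ent;
    }
  }
  return out;
}

// Per-pixel tonal range (max - min) of a (window x window) neighborhood,
// replicate boundary padding.
// [[Rcpp::export]]
IntegerMatrix range_filter_cpp(IntegerMatrix img, int window) {
  const int h = img.nrow(), w = img.ncol();
  const int r = window / 2;
  IntegerMatrix out(h, w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      int lo = 65535, hi = 0;
      for (int di = -r; di <= r; ++di) {
        const int ii = clamp_idx(i + di, h);
        for (int dj = -r; dj <= r; ++dj) {
          const int v = img(ii, clamp_idx(j + dj, w));
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      }
      out(i, j) = hi - lo;
    }
  }
  return out;
}

// Reverse PNG scanline filtering. `data` holds height rows of
// (1 + rowbytes) bytes each: a filter-type byte followed by the filtered
// scanline. `bpp` is bytes per complete pixel. Returns height * rowbytes
// raw bytes of reconstructed image data.
// [[Rcpp::export]]
RawVector png_unfilter_cpp(RawVector data, int height, int rowbytes, int bpp) {
  if ((R_xlen_t)height * (rowbytes + 1) > data.size())
    stop("PNG image data is truncated");
  RawVector out((R_xlen_t)height * rowbytes);
  std::vector<unsigned char> prev(rowbytes, 0), cur(rowbytes, 0);
  R_xlen_t pos = 0;
  for (int y = 0; y < height; ++y) {
    const int ftype = data[pos++];
    for (int x = 0; x < rowbytes; ++x) cur[x] = data[pos++];
    switch (ftype) {
    case 0: break;
    case 1: // Sub
      for (int x = bpp; x < rowbytes; ++x) cur[x] = (unsigned char)(cur[x] + cur[x - bpp]);
      break;
    case 2: // Up
      for (int x = 0; x < rowbytes; ++x) cur[x] = (unsigned char)(cur[x] + prev[x]);
      break;
    case 3: // Average
      for (int x = 0; x < rowbytes; ++x) {
        const int a = x >= bpp ? cur[x - bpp] : 0;
        cur[x] = (unsigned char)(cur[x] + ((a + prev[x]) >> 1));
      }
      break;
    case 4: // Paeth
      for (int x = 0; x < rowbytes; ++x) {
        const int a = x >= bpp ? cur[x - bpp] : 0;
        const int b = prev[x];
        const int c = x >= bpp ? prev[x - bpp] : 0;
        const int p = a + b - c;
        const int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
        int pr = (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
        cur[x] = (unsigned char)(cur[x] + pr);
      }
      break;
    default:
      stop("unsupported PNG filter type %d", ftype);
    }
    for (int x = 0; x < rowbytes; ++x) out[(R_xlen_t)y * rowbytes + x] = cur[x];
    prev.swap(cur);
  }
  return out;
}
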