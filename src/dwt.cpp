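#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Periodic (circular) orthonormal 2-D discrete wavelet transform.
//
// The quadrature-mirror highpass is g[t] = (-1)^t h[T-1-t].  With periodic
// boundary handling and every level's input length >= T the transform matrix
// is orthogonal, so the inverse below is the exact transpose: applying
// idwt2_per after dwt2_per reproduces the input to machine precision, and
// idwt2_per is the adjoint of dwt2_per for any coefficient vector.
//
// Coefficients use the in-place quadrant layout: after each level the leading
// s x s block holds [LL LH; HL HH] and recursion continues on LL.

static void fwd_cols(std::vector<double>& buf, double* x, int s, int ld,
                     const std::vector<double>& h, const std::vector<double>& g,
                     int ncol) {
  const int T = (int)h.size();
  const int half = s / 2;
  for (int c = 0; c < ncol; ++c) {
    double* col = x + (size_t)c * ld;
    for (int k = 0; k < half; ++k) {
      double a = 0.0, d = 0.0;
      int base = 2 * k;
      for (int t = 0; t < T; ++t) {
        int i = base + t;
        if (i >= s) i -= s;            // T <= s so one wrap suffices
        a += h[t] * col[i];
        d += g[t] * col[i];
      }
      buf[k] = a;
      buf[half + k] = d;
    }
    std::copy(buf.begin(), buf.begin() + s, col);
  }
}

static void inv_cols(std::vector<double>& buf, double* x, int s, int ld,
                     const std::vector<double>& h, const std::vector<double>& g,
                     int ncol) {
  const int T = (int)h.size();
  const int half = s / 2;
  for (int c = 0; c < ncol; ++c) {
    double* col = x + (size_t)c * ld;
    std::fill(buf.begin(), buf.begin() + s, 0.0);
    for (int k = 0; k < half; ++k) {
      const double a = col[k], d = col[half + k];
      int base = 2 * k;
      for (int t = 0; t < T; ++t) {
        int i = base + t;
        if (i >= s) i -= s;
        buf[i] += h[t] * a + g[t] * d;
      }
    }
    std::copy(buf.begin(), buf.begin() + s, col);
  }
}

static void transpose_block(double* x, int s, int ld, std::vector<double>& tmp) {
  for (int c = 0; c < s; ++c)
    for (int r = 0; r < s; ++r)
      tmp[(size_t)r * s + c] = x[(size_t)c * ld + r];
  for (int c = 0; c < s; ++c)
    std::copy(tmp.begin() + (size_t)c * s, tmp.begin() + (size_t)(c + 1) * s,
              x + (size_t)c * ld);
}

static std::vector<double> qmf(const std::vector<double>& h) {
  const int T = (int)h.size();
  std::vector<double> g(T);
  for (int t = 0; t < T; ++t)
    g[t] = ((t % 2) ? -1.0 : 1.0) * h[T - 1 - t];
  return g;
}

// [[Rcpp::export]]
NumericMatrix dwt2_per(NumericMatrix x, NumericVector filter, int levels) {
  const int N = x.nrow();
  if (x.ncol() != N) stop("image must be square");
  std::vector<double> h(filter.begin(), filter.end());
  std::vector<double> g = qmf(h);
  const int T = (int)h.size();
  NumericMatrix w = clone(x);
  std::vector<double> buf(N), tmp((size_t)N * N);
  int s = N;
  for (int lev = 0; lev < levels; ++lev) {
    if (s % 2 != 0 || s < T)
      stop("level %d input length %d incompatible with filter length %d",
           lev + 1, s, T);
    // columns, then rows of the leading s x s block
    fwd_cols(buf, w.begin(), s, N, h, g, s);
    transpose_block(w.begin(), s, N, tmp);
    fwd_cols(buf, w.begin(), s, N, h, g, s);
    transpose_block(w.begin(), s, N, tmp);
    s /= 2;
  }
  return w;
}

// [[Rcpp::export]]
NumericMatrix idwt2_per(NumericMatrix w, NumericVector filter, int levels) {
  const int N = w.nrow();
  if (w.ncol() != N) stop("coefficient array must be square");
  std::vector<double> h(filter.begin(), filter.end());
  std::vector<double> g = qmf(h);
  NumericMatrix x = clone(w);
  std::vector<double> buf(N), tmp((size_t)N * N);
  for (int lev = levels - 1; lev >= 0; --lev) {
    int s = N >> lev;
    // undo rows, then columns (mirror of the forward order)
    transpose_block(x.begin(), s, N, tmp);
    inv_cols(buf, x.begin(), s, N, h, g, s);
    transpose_block(x.begin(), s, N, tmp);
    inv_cols(buf, x.begin(), s, N, h, g, s);
  }
  return x;
}
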