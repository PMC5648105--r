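#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson correlation over nlen samples; false when either side has zero
// variance (the caller skips that lag).
static inline bool pearson(const double* x, const double* y, int nlen,
                           double& r) {
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < nlen; i++) { sx += x[i]; sy += y[i]; }
  const double mx = sx / nlen, my = sy / nlen;
  double vxx = 0.0, vyy = 0.0, vxy = 0.0;
  for (int i = 0; i < nlen; i++) {
    const double dx = x[i] - mx, dy = y[i] - my;
    vxx += dx * dx; vyy += dy * dy; vxy += dx * dy;
  }
  if (vxx <= 0.0 || vyy <= 0.0) return false;
  r = vxy / std::sqrt(vxx * vyy);
  return true;
}

// Scan one ordered signal pair over all window starts and integer lags.
// a, b: full epoch signals (same length S). starts: 0-based window starts.
// For window start s and lag phi, x = a[s .. s+w), y = b[s+phi .. s+phi+w)
// clipped to the epoch; the overlap must hold at least min_overlap samples.
// Lags are visited in the order 0, -1, +1, -2, +2, ... and a candidate
// replaces the incumbent only when strictly larger, so ties resolve to the
// smallest |phi| and then to the negative lag; earlier window starts win
// ties across windows.
static bool scan_pair(const double* a, const double* b, int S,
                      const int* starts, int nstarts, int w, int lag_max,
                      int min_overlap, double& best_r, int& best_lag,
                      int& best_start) {
  bool any = false;
  best_r = R_NegInf; best_lag = NA_INTEGER; best_start = NA_INTEGER;
  for (int si = 0; si < nstarts; si++) {
    const int s = starts[si];
    for (int k = 0; k <= 2 * lag_max; k++) {
      // 0, -1, +1, -2, +2, ...
      const int phi = (k % 2 == 1) ? -((k + 1) / 2) : (k / 2);
      int t0 = 0, t1 = w - 1;
      if (s + phi < 0) t0 = -(s + phi);
      if (s + phi + t1 > S - 1) t1 = S - 1 - s - phi;
      const int nlen = t1 - t0 + 1;
      if (nlen < min_overlap) continue;
      double r;
      if (!pearson(a + s + t0, b + s + phi + t0, nlen, r)) continue;
      any = true;
      if (r > best_r) { best_r = r; best_lag = phi; best_start = s; }
    }
  }
  return any;
}

// [[Rcpp::export]]
List lag_scan_pair_cpp(NumericVector a, NumericVector b, IntegerVector starts,
                       int w, int lag_max, int min_overlap) {
  const int S = b.size();
  double r; int lag, st;
  bool ok = scan_pair(REAL(a), REAL(b), S, INTEGER(starts), starts.size(), w,
                      lag_max, min_overlap, r, lag, st);
  return List::create(_["ok"] = ok, _["r"] = ok ? r : NA_REAL,
                      _["lag"] = lag, _["start"] = st);
}

// Full channel-by-channel scan for one subject: X is channels x samples.
// Each unordered pair is scanned once (windows anchored on the first
// channel, the second drawn from the full epoch) and mirrored, so the
// matrix is symmetric by construction with antisymmetric lags; the
// diagonal is fixed at 1.
// [[Rcpp::export]]
List lag_scan_matrix_cpp(NumericMatrix X, IntegerVector starts, int w,
                         int lag_max, int min_overlap) {
  const int n = X.nrow(), S = X.ncol();
  NumericMatrix R(n, n);
  IntegerMatrix L(n, n);
  LogicalMatrix OK(n, n);
  // copy rows to contiguous buffers (X is column-major)
  std::vector<double> buf((size_t)n * S);
  for (int c = 0; c < n; c++)
    for (int t = 0; t < S; t++) buf[(size_t)c * S + t] = X(c, t);
  for (int i = 0; i < n; i++) { R(i, i) = 1.0; L(i, i) = 0; OK(i, i) = true; }
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double r; int lag, st;
      bool ok = scan_pair(&buf[(size_t)i * S], &buf[(size_t)j * S], S,
                          INTEGER(starts), starts.size(), w, lag_max,
                          min_overlap, r, lag, st);
      OK(i, j) = OK(j, i) = ok;
      R(i, j) = R(j, i) = ok ? r : NA_REAL;
      L(i, j) = ok ? lag : NA_INTEGER;
      L(j, i) = ok ? -lag : NA_INTEGER;
    }
  }
  return List::create(_["r"] = R, _["lag"] = L, _["ok"] = OK);
}
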