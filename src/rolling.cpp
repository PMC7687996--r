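#include <Rcpp.h>
using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted vector.
static double q_type7(const std::vector<double>& v, double p) {
  int m = v.size();
  if (m == 1) return v[0];
  double h = (m - 1.0) * p;
  int lo = (int)std::floor(h);
  if (lo + 1 >= m) return v[m - 1];
  double g = h - lo;
  return v[lo] + g * (v[lo + 1] - v[lo]);
}

// Rolling window features over a regular 1-minute grid.
//
// For every end position t (0-based minute t = row t-1 in R) with a full
// window [t-window+1, t] available, computes summary statistics over the
// present (non-NA) values, magnitudes of the first n_dft non-constant DFT
// coefficients of the mean-filled demeaned window, and the EWMA of the
// present values in chronological order.
//
// Column layout (0-based): 0 mean, 1 var (sample, NA if <2 present),
// 2 min, 3 max, 4 q1, 5 median, 6 q3, 7..6+n_dft DFT magnitudes,
// 7+n_dft ewma, 8+n_dft count of present values.
// Rows with no full window, zero present values, or completeness below
// min_completeness are NA except for the count column.
// [[Rcpp::export]]
NumericMatrix cpp_roll_features(NumericVector x, int window, int n_dft,
                                double ewma_alpha, double min_completeness) {
  int n = x.size();
  int ncol = 9 + n_dft;
  NumericMatrix out(n, ncol);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> w;
  w.reserve(window);
  for (int t = window - 1; t < n; ++t) {
    w.clear();
    for (int j = t - window + 1; j <= t; ++j)
      if (!NumericVector::is_na(x[j])) w.push_back(x[j]);
    int m = (int)w.size();
    out(t, 8 + n_dft) = m;
    if (m == 0 || (double)m / window < min_completeness) continue;
    double s = 0.0;
    for (double v : w) s += v;
    double mean = s / m;
    double var = NA_REAL;
    if (m >= 2) {
      double ss = 0.0;
      for (double v : w) ss += (v - mean) * (v - mean);
      var = ss / (m - 1);
    }
    std::vector<double> srt(w);
    std::sort(srt.begin(), srt.end());
    out(t, 0) = mean;
    out(t, 1) = var;
    out(t, 2) = srt.front();
    out(t, 3) = srt.back();
    out(t, 4) = q_type7(srt, 0.25);
    out(t, 5) = q_type7(srt, 0.50);
    out(t, 6) = q_type7(srt, 0.75);
    // DFT of the window with missing minutes filled by the window mean and
    // the mean subtracted, so filled minutes contribute zero.
    for (int k = 1; k <= n_dft; ++k) {
      double re = 0.0, im = 0.0;
      for (int j = 0; j < window; ++j) {
        double xv = x[t - window + 1 + j];
        double y = NumericVector::is_na(xv) ? 0.0 : xv - mean;
        double ang = -2.0 * M_PI * (double)j * (double)k / (double)window;
        re += y * std::cos(ang);
        im += y * std::sin(ang);
      }
      out(t, 6 + k) = std::sqrt(re * re + im * im);
    }
    double sm = w[0];
    for (int j = 1; j < m; ++j) sm = ewma_alpha * w[j] + (1.0 - ewma_alpha) * sm;
    out(t, 7 + n_dft) = sm;
  }
  return out;
}
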