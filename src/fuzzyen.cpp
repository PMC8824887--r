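#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mean exponential similarity exp(-(d/r)^grad) over all ordered template
// pairs, Chebyshev distance on baseline-removed windows of length `wlen`.
// `M` templates are used regardless of `wlen` so the counts at embedding
// dimensions m and m+1 match.
static double phi_scale(const std::vector<double>& x, int wlen, int M,
                        double r, double grad) {
  // window means via prefix sums
  std::vector<double> mu(M);
  double acc = 0.0;
  for (int t = 0; t < wlen; ++t) acc += x[t];
  mu[0] = acc / wlen;
  for (int i = 1; i < M; ++i) {
    acc += x[i + wlen - 1] - x[i - 1];
    mu[i] = acc / wlen;
  }
  double sum = 0.0;
  const bool quad = (grad == 2.0);
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = 0.0;
      for (int t = 0; t < wlen; ++t) {
        double diff = std::fabs((x[i + t] - mu[i]) - (x[j + t] - mu[j]));
        if (diff > d) d = diff;
      }
      double u = d / r;
      sum += std::exp(quad ? -(u * u) : -std::pow(u, grad));
    }
  }
  return 2.0 * sum / (static_cast<double>(M) * (M - 1));
}

static double fuzzyen_one(const std::vector<double>& x, int m, double r,
                          double grad) {
  int N = static_cast<int>(x.size());
  int M = N - m;  // templates shared by scales m and m+1
  if (M < 2) return NA_REAL;
  double phi_m = phi_scale(x, m, M, r, grad);
  double phi_m1 = phi_scale(x, m + 1, M, r, grad);
  if (phi_m <= 0.0 || phi_m1 <= 0.0) return NA_REAL;
  return std::log(phi_m) - std::log(phi_m1);
}

// [[Rcpp::export]]
double cpp_fuzzyen(NumericVector x, int m, double r, double gradient) {
  if (r <= 0.0) stop("tolerance r must be positive");
  std::vector<double> v(x.begin(), x.end());
  return fuzzyen_one(v, m, r, gradient);
}

// Per-row fuzzy entropy of a block of series; r = r_factor * sample SD of
// the row. Rows with zero SD yield NA.
// [[Rcpp::export]]
NumericVector cpp_fuzzyen_block(NumericMatrix series, int m, double r_factor,
                                double gradient) {
  int n_series = series.nrow(), n = series.ncol();
  NumericVector out(n_series);
  std::vector<double> v(n);
  for (int i = 0; i < n_series; ++i) {
    double s = 0.0, ss = 0.0;
    for (int t = 0; t < n; ++t) {
      v[t] = series(i, t);
      s += v[t];
      ss += v[t] * v[t];
    }
    double var = (ss - s * s / n) / (n - 1);
    if (var <= 0.0) {
      out[i] = NA_REAL;
      continue;
    }
    out[i] = fuzzyen_one(v, m, r_factor * std::sqrt(var), gradient);
  }
  return out;
}
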