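#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Empirical mode decomposition sifting core.
//
// Envelopes are natural cubic splines through the local extrema, with the
// extrema mirrored about both ends of the record so that end effects do not
// bend the envelopes inside the data window.  Sifting stops on a Cauchy-type
// criterion sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh, capped at
// max_sift iterations.

// Local extrema of x; plateaus contribute their midpoint.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima, std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    double dprev = x[i] - x[i - 1];
    if (dprev == 0.0) { ++i; continue; }
    int j = i;
    while (j < n - 1 && x[j + 1] == x[j]) ++j;   // plateau [i, j]
    if (j >= n - 1) break;
    double dnext = x[j + 1] - x[j];
    int mid = (i + j) / 2;
    if (dprev > 0.0 && dnext < 0.0) maxima.push_back(mid);
    else if (dprev < 0.0 && dnext > 0.0) minima.push_back(mid);
    i = j + 1;
  }
}

// Natural cubic spline through (t, y), evaluated at integers 0..n-1.
// Knots are strictly increasing; t may extend beyond [0, n-1].
static void spline_eval(const std::vector<double>& t, const std::vector<double>& y,
                        int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 2) {           // straight line
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int k = 0; k < n; ++k) out[k] = y[0] + slope * (k - t[0]);
    return;
  }
  // second derivatives M via Thomas algorithm, natural BCs M[0]=M[m-1]=0
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 3.0 * ((y[k + 1] - y[k]) / h[k] - (y[k] - y[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (t[k + 1] - t[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  M[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) M[k] = z[k] - mu[k] * M[k + 1];

  int seg = 0;
  for (int k = 0; k < n; ++k) {
    double xx = (double)k;
    while (seg < m - 2 && t[seg + 1] < xx) ++seg;
    double hk = t[seg + 1] - t[seg];
    double A = (t[seg + 1] - xx) / hk, B = (xx - t[seg]) / hk;
    out[k] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * (hk * hk) / 6.0;
  }
}

// Extrema mirrored about samples 0 and n-1 (up to two on each side).
static void mirror_knots(const std::vector<int>& idx, const std::vector<double>& x,
                         int n, std::vector<double>& t, std::vector<double>& y) {
  const int m = (int)idx.size();
  t.clear(); y.clear();
  for (int j = std::min(2, m) - 1; j >= 0; --j) {
    if (idx[j] > 0) { t.push_back(-(double)idx[j]); y.push_back(x[idx[j]]); }
  }
  for (int j = 0; j < m; ++j) { t.push_back((double)idx[j]); y.push_back(x[idx[j]]); }
  for (int j = 0; j < std::min(2, m); ++j) {
    int k = m - 1 - j;
    if (idx[k] < n - 1) { t.push_back(2.0 * (n - 1) - idx[k]); y.push_back(x[idx[k]]); }
  }
  // enforce strict monotonicity (duplicates possible for extrema at the ends)
  std::vector<double> tt, yy;
  for (size_t j = 0; j < t.size(); ++j) {
    if (tt.empty() || t[j] > tt.back()) { tt.push_back(t[j]); yy.push_back(y[j]); }
  }
  t.swap(tt); y.swap(yy);
}

// One sifting pass: h -> h - mean_envelope(h).  Returns false when h has
// too few extrema to build envelopes (i.e. h is a residual, not an IMF).
static bool mean_envelope(const std::vector<double>& h, std::vector<double>& menv) {
  const int n = (int)h.size();
  std::vector<int> maxima, minima;
  find_extrema(h, maxima, minima);
  if ((int)maxima.size() < 2 || (int)minima.size() < 2) return false;
  std::vector<double> t, y, upper, lower;
  mirror_knots(maxima, h, n, t, y);
  spline_eval(t, y, n, upper);
  mirror_knots(minima, h, n, t, y);
  spline_eval(t, y, n, lower);
  menv.resize(n);
  for (int k = 0; k < n; ++k) menv[k] = 0.5 * (upper[k] + lower[k]);
  return true;
}

// Sift one IMF out of x.  Returns false when x carries no oscillatory mode.
static bool sift_imf(const std::vector<double>& x, double sd_thresh, int max_sift,
                     std::vector<double>& imf) {
  const int n = (int)x.size();
  imf = x;
  std::vector<double> menv(n);
  for (int it = 0; it < max_sift; ++it) {
    if (!mean_envelope(imf, menv)) return it > 0;  // stopped mid-sift: keep h
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n; ++k) {
      num += menv[k] * menv[k];
      den += imf[k] * imf[k];
      imf[k] -= menv[k];
    }
    if (den <= 0.0) return false;
    if (num / den < sd_thresh) return true;
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".emd_c")]]
List emd_c(NumericVector x, int max_imfs, double sd_thresh, int max_sift) {
  const int n = x.size();
  std::vector<double> resid(x.begin(), x.end()), imf;
  std::vector<std::vector<double> > imfs;
  for (int k = 0; k < max_imfs; ++k) {
    if (!sift_imf(resid, sd_thresh, max_sift, imf)) break;
    imfs.push_back(imf);
    for (int j = 0; j < n; ++j) resid[j] -= imf[j];
  }
  NumericMatrix M(n, (int)imfs.size());
  for (size_t c = 0; c < imfs.size(); ++c)
    std::copy(imfs[c].begin(), imfs[c].end(), M.begin() + c * n);
  return List::create(_["imfs"] = M, _["residual"] = NumericVector(resid.begin(), resid.end()));
}

// First IMF only (CEEMDAN inner call); zero vector when none exists.
//' @noRd
// [[Rcpp::export(name = ".first_imf_c")]]
NumericVector first_imf_c(NumericVector x, double sd_thresh, int max_sift) {
  std::vector<double> xi(x.begin(), x.end()), imf;
  if (!sift_imf(xi, sd_thresh, max_sift, imf))
    return NumericVector(x.size());
  return NumericVector(imf.begin(), imf.end());
}

// Number of local extrema (used for stopping rules at the R level).
//' @noRd
// [[Rcpp::export(name = ".n_extrema_c")]]
int n_extrema_c(NumericVector x) {
  std::vector<double> xi(x.begin(), x.end());
  std::vector<int> maxima, minima;
  find_extrema(xi, maxima, minima);
  return (int)(maxima.size() + minima.size());
}
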