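#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nonzero runs of a series, as half-open [start, end) index pairs (0-based).
// Binned predictors are mostly zero outside their level's support, so all
// correlation loops below walk runs instead of the full record.  Runs closer
// than `gap` samples are merged (multiplying through the few enclosed zeros
// is cheaper than tracking millions of one-sample runs when the series
// itself is sparse, e.g. a rectified-noise carrier).
static void nonzero_runs(const NumericVector& x,
                         std::vector<int>& starts, std::vector<int>& ends,
                         int gap = 512) {
  int n = x.size();
  int i = 0;
  while (i < n) {
    if (x[i] != 0.0) {
      int s = i;
      while (i < n && x[i] != 0.0) ++i;
      if (!starts.empty() && s - ends.back() < gap) ends.back() = i;
      else { starts.push_back(s); ends.push_back(i); }
    } else {
      ++i;
    }
  }
}

// Full cross-correlation C(d) = sum_m a[m] * b[m + d] for d in [dmin, dmax],
// restricted to the nonzero runs of both series (two-pointer intersection of
// the runs of a with the runs of b shifted by -d).
static void cross_corr_runs(const NumericVector& a, const NumericVector& b,
                            const std::vector<int>& as, const std::vector<int>& ae,
                            const std::vector<int>& bs, const std::vector<int>& be,
                            int dmin, int dmax, bool symmetric,
                            std::vector<double>& out) {
  const int nd = dmax - dmin + 1;
  out.assign(nd, 0.0);
  const int nra = (int)as.size(), nrb = (int)bs.size();
  const double* pa = &a[0];
  const double* pb = &b[0];
  for (int d = dmin; d <= dmax; ++d) {
    if (symmetric && d < 0) continue; // autocorrelation: C(-d) = C(d)
    double acc = 0.0;
    int ia = 0, ib = 0;
    const double* pbd = pb + d;
    while (ia < nra && ib < nrb) {
      int s1 = as[ia], e1 = ae[ia];
      int s2 = bs[ib] - d, e2 = be[ib] - d; // b run in m-coordinates
      int lo = s1 > s2 ? s1 : s2;
      int hi = e1 < e2 ? e1 : e2;
      for (int m = lo; m < hi; ++m) acc += pa[m] * pbd[m];
      if (e1 < e2) ++ia; else ++ib;
    }
    out[d - dmin] = acc;
  }
  if (symmetric)
    for (int d = dmin; d < 0; ++d) out[d - dmin] = out[-d - dmin];
}

// X'X for the joint lagged regression.  Column (l, k) of the design matrix
// holds x_l[n - k] with zeros outside the record (n = 0..N-1 rows only).
// Entry = full cross-correlation at lag (k - k') minus the boundary rows
// (n < 0 or n >= N) that the full correlation counts but the design matrix
// does not; those trims involve at most max(|kmin|, kmax) samples per entry.
// [[Rcpp::export]]
NumericMatrix cpp_xtx_lagged(List preds, int kmin, int kmax) {
  const int L = preds.size();
  const int K = kmax - kmin + 1;
  NumericMatrix M(K * L, K * L);
  std::vector<NumericVector> xs(L);
  std::vector<std::vector<int> > rs(L), re(L);
  int N = -1;
  for (int l = 0; l < L; ++l) {
    xs[l] = as<NumericVector>(preds[l]);
    if (N < 0) N = xs[l].size();
    else if ((int)xs[l].size() != N) stop("binned predictors differ in length");
    nonzero_runs(xs[l], rs[l], re[l]);
  }
  const int dmin = kmin - kmax, dmax = kmax - kmin;
  std::vector<double> C;
  for (int a = 0; a < L; ++a) {
    for (int b = a; b < L; ++b) {
      cross_corr_runs(xs[a], xs[b], rs[a], re[a], rs[b], re[b], dmin, dmax,
                      a == b, C);
      for (int k = kmin; k <= kmax; ++k) {
        int k2min = (a == b) ? k : kmin;
        for (int k2 = k2min; k2 <= kmax; ++k2) {
          double v = C[(k - k2) - dmin];
          if (k < 0 && k2 < 0) {          // rows n < 0 counted by C, not by X
            int n0 = k > k2 ? k : k2;
            for (int n = n0; n < 0; ++n) v -= xs[a][n - k] * xs[b][n - k2];
          } else if (k > 0 && k2 > 0) {   // rows n >= N counted by C, not by X
            int n1 = (k < k2 ? k : k2) + N - 1;
            for (int n = N; n <= n1; ++n) v -= xs[a][n - k] * xs[b][n - k2];
          }
          int i = a * K + (k - kmin), j = b * K + (k2 - kmin);
          M(i, j) = v;
          M(j, i) = v;
        }
      }
    }
  }
  return M;
}

// X'y for the same design: B[(l, k)] = sum_m x_l[m] * y[m + k].
// [[Rcpp::export]]
NumericVector cpp_xty_lagged(List preds, NumericVector y, int kmin, int kmax) {
  const int L = preds.size();
  const int K = kmax - kmin + 1;
  const int N = y.size();
  NumericVector B(K * L);
  for (int l = 0; l < L; ++l) {
    NumericVector x = as<NumericVector>(preds[l]);
    if ((int)x.size() != N) stop("predictor/EEG length mismatch");
    std::vector<int> rs, re;
    nonzero_runs(x, rs, re);
    const double* px = &x[0];
    const double* py = &y[0];
    for (int k = kmin; k <= kmax; ++k) {
      int mlo = k < 0 ? -k : 0;
      int mhi = k > 0 ? N - k : N;
      double acc = 0.0;
      const double* pyk = py + k;
      for (size_t r = 0; r < rs.size(); ++r) {
        int lo = rs[r] > mlo ? rs[r] : mlo;
        int hi = re[r] < mhi ? re[r] : mhi;
        for (int m = lo; m < hi; ++m) acc += px[m] * pyk[m];
      }
      B[l * K + (k - kmin)] = acc;
    }
  }
  return B;
}

// One gammatone band: fourth-order filter realized as four cascaded complex
// one-pole sections with pole radius exp(-2*pi*b/fs) at centre frequency fc.
// Returns the magnitude of the final complex signal (the band envelope),
// normalized to unit gain at fc.
// [[Rcpp::export]]
NumericVector cpp_gammatone_env(NumericVector x, double fs, double fc, double b) {
  const int n = x.size();
  const double r = std::exp(-2.0 * M_PI * b / fs);
  const double w = 2.0 * M_PI * fc / fs;
  const double pre = r * std::cos(w), pim = r * std::sin(w);
  const double gain = std::pow(1.0 - r, 4.0); // each stage has gain 1/(1-r) at fc
  std::vector<double> sre(4, 0.0), sim(4, 0.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vre = x[i], vim = 0.0;
    for (int s = 0; s < 4; ++s) {
      double nre = vre + pre * sre[s] - pim * sim[s];
      double nim = vim + pre * sim[s] + pim * sre[s];
      sre[s] = nre; sim[s] = nim;
      vre = nre; vim = nim;
    }
    out[i] = gain * std::sqrt(vre * vre + vim * vim);
  }
  return out;
}
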