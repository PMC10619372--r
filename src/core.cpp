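#include <Rcpp.h>
#include <complex>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::complex<double> cplx;

// windowed |Im(mean(exp(i(ph1 - ph2))))| via complex prefix sums
// [[Rcpp::export]]
NumericVector windowed_iplv_cpp(NumericVector ph1, NumericVector ph2,
                                IntegerVector starts, int width) {
  int n = ph1.size();
  if (ph2.size() != n) stop("phase series lengths differ");
  std::vector<cplx> cs(n + 1, cplx(0.0, 0.0));
  for (int t = 0; t < n; ++t) {
    double d = ph1[t] - ph2[t];
    cs[t + 1] = cs[t] + cplx(std::cos(d), std::sin(d));
  }
  int nw = starts.size();
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    int s = starts[w] - 1;
    if (s < 0 || s + width > n) stop("window outside the recording");
    cplx m = (cs[s + width] - cs[s]) / double(width);
    out[w] = std::fabs(m.imag());
  }
  return out;
}

// pooled single-cut surrogate values for one pair of phase series: one signal
// is circularly rotated over the FULL recording (the single-cut swap), the
// windowed statistic recomputed; rotations stay >= margin samples from zero
// [[Rcpp::export]]
NumericVector rotation_null_cpp(NumericVector ph1, NumericVector ph2,
                                IntegerVector starts, int width, int n_draws,
                                double margin_frac, bool rotate_first) {
  int n = ph1.size();
  if (ph2.size() != n) stop("phase series lengths differ");
  int margin = std::max(width, (int)std::floor(margin_frac * n));
  if (2 * margin >= n) stop("recording too short for the rotation margin");
  int nw = starts.size();
  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d) {
    int w = (int)std::floor(unif_rand() * nw);
    if (w == nw) w = nw - 1;
    int s = starts[w] - 1;
    int r = margin + (int)std::floor(unif_rand() * (n - 2 * margin));
    cplx acc(0.0, 0.0);
    for (int t = 0; t < width; ++t) {
      int tr = (s + t + r) % n;
      double dd = rotate_first ? (ph1[tr] - ph2[s + t]) : (ph1[s + t] - ph2[tr]);
      acc += cplx(std::cos(dd), std::sin(dd));
    }
    out[d] = std::fabs(acc.imag() / double(width));
  }
  return out;
}

static inline double pval_from_sorted(const std::vector<double>& nullv, double obs) {
  int n = nullv.size();
  int lo = std::lower_bound(nullv.begin(), nullv.end(), obs) - nullv.begin();
  return (1.0 + (n - lo)) / (1.0 + n);
}

// Full dynamic-FCG construction with pooled per-mode surrogate nulls.
// band_phases: list of 8 (N x R) phase matrices (analytic phase per band);
// env_phases: list of 28 (N x R) matrices (low-band phase of the high-band
// amplitude envelope, one per cross-frequency combo);
// combos: 28 x 2 matrix of 1-based (low, high) band indices;
// starts: 1-based window starts; width: window width in samples.
// Returns strengths and p-values as (36, W, R, R) arrays plus the sorted
// pooled null per mode.
// [[Rcpp::export]]
List dfcg_core_cpp(List band_phases, List env_phases, IntegerMatrix combos,
                   IntegerVector starts, int width, int n_null,
                   double margin_frac) {
  const int n_bands = band_phases.size();
  const int n_cross = env_phases.size();
  if (n_bands != 8 || n_cross != 28) stop("expected 8 bands and 28 cross combos");
  NumericMatrix ph0 = band_phases[0];
  const int N = ph0.nrow(), R = ph0.ncol();
  const int nw = starts.size();
  const int n_modes = n_bands + n_cross;

  // unit phasors per band/roi and per combo/roi
  std::vector< std::vector<cplx> > zb(n_bands), ze(n_cross);
  for (int b = 0; b < n_bands; ++b) {
    NumericMatrix ph = band_phases[b];
    if (ph.nrow() != N || ph.ncol() != R) stop("band phase dims differ");
    zb[b].resize((size_t)N * R);
    for (int r = 0; r < R; ++r)
      for (int t = 0; t < N; ++t)
        zb[b][(size_t)r * N + t] = cplx(std::cos(ph(t, r)), std::sin(ph(t, r)));
  }
  for (int c = 0; c < n_cross; ++c) {
    NumericMatrix ph = env_phases[c];
    if (ph.nrow() != N || ph.ncol() != R) stop("envelope phase dims differ");
    ze[c].resize((size_t)N * R);
    for (int r = 0; r < R; ++r)
      for (int t = 0; t < N; ++t)
        ze[c][(size_t)r * N + t] = cplx(std::cos(ph(t, r)), std::sin(ph(t, r)));
  }

  const size_t modeblock = (size_t)nw * R * R;
  NumericVector strengths(n_modes * modeblock);  // dim (36, W, R, R) later
  std::vector<cplx> cs(N + 1);

  // observed: within-frequency iPLV (symmetric)
  for (int b = 0; b < n_bands; ++b) {
    for (int i = 0; i < R; ++i) {
      const cplx* zi = &zb[b][(size_t)i * N];
      for (int j = i + 1; j < R; ++j) {
        const cplx* zj = &zb[b][(size_t)j * N];
        cs[0] = cplx(0.0, 0.0);
        for (int t = 0; t < N; ++t) cs[t + 1] = cs[t] + zi[t] * std::conj(zj[t]);
        for (int w = 0; w < nw; ++w) {
          int s = starts[w] - 1;
          double v = std::fabs((cs[s + width] - cs[s]).imag() / double(width));
          strengths[b + n_modes * (w + (size_t)nw * (i + (size_t)R * j))] = v;
          strengths[b + n_modes * (w + (size_t)nw * (j + (size_t)R * i))] = v;
        }
      }
    }
  }
  // observed: cross-frequency PAC, directed i (phase) -> j (amplitude)
  for (int c = 0; c < n_cross; ++c) {
    int lb = combos(c, 0) - 1;
    int m = n_bands + c;
    for (int i = 0; i < R; ++i) {
      const cplx* zi = &zb[lb][(size_t)i * N];
      for (int j = 0; j < R; ++j) {
        if (j == i) continue;
        const cplx* wj = &ze[c][(size_t)j * N];
        cs[0] = cplx(0.0, 0.0);
        for (int t = 0; t < N; ++t) cs[t + 1] = cs[t] + zi[t] * std::conj(wj[t]);
        for (int w = 0; w < nw; ++w) {
          int s = starts[w] - 1;
          double v = std::fabs((cs[s + width] - cs[s]).imag() / double(width));
          strengths[m + n_modes * (w + (size_t)nw * (i + (size_t)R * j))] = v;
        }
      }
    }
  }

  // pooled null per mode: random pair, window and full-recording rotation
  // (single-cut swap of one signal's phase sequence; for PAC the
  // envelope-phase side is cut)
  int margin = std::max(width, (int)std::floor(margin_frac * N));
  if (2 * margin >= N) stop("recording too short for the rotation margin");
  List nulls(n_modes);
  std::vector< std::vector<double> > nullv(n_modes);
  for (int m = 0; m < n_modes; ++m) {
    nullv[m].resize(n_null);
    bool intra = m < n_bands;
    for (int d = 0; d < n_null; ++d) {
      int i = (int)std::floor(unif_rand() * R); if (i == R) i = R - 1;
      int j = (int)std::floor(unif_rand() * (R - 1)); if (j >= i) j += 1;
      int w = (int)std::floor(unif_rand() * nw); if (w == nw) w = nw - 1;
      int s = starts[w] - 1;
      int r = margin + (int)std::floor(unif_rand() * (N - 2 * margin));
      const cplx *z1, *z2;
      bool rot_first;
      if (intra) {
        z1 = &zb[m][(size_t)i * N];
        z2 = &zb[m][(size_t)j * N];
        rot_first = unif_rand() < 0.5;  // either virtual source may be cut
      } else {
        int c = m - n_bands;
        int lb = combos(c, 0) - 1;
        z1 = &zb[lb][(size_t)i * N];
        z2 = &ze[c][(size_t)j * N];
        rot_first = false;  // always cut the amplitude-bearing series
      }
      cplx acc(0.0, 0.0);
      for (int t = 0; t < width; ++t) {
        int tr = (s + t + r) % N;
        acc += rot_first ? z1[tr] * std::conj(z2[s + t])
                         : z1[s + t] * std::conj(z2[tr]);
      }
      nullv[m][d] = std::fabs(acc.imag() / double(width));
    }
    std::sort(nullv[m].begin(), nullv[m].end());
    nulls[m] = NumericVector(nullv[m].begin(), nullv[m].end());
  }

  // p-values
  NumericVector pvals(n_modes * modeblock);
  std::fill(pvals.begin(), pvals.end(), 1.0);
  for (int m = 0; m < n_modes; ++m) {
    for (int j = 0; j < R; ++j)
      for (int i = 0; i < R; ++i) {
        if (i == j) continue;
        for (int w = 0; w < nw; ++w) {
          size_t idx = m + n_modes * (w + (size_t)nw * (i + (size_t)R * j));
          pvals[idx] = pval_from_sorted(nullv[m], strengths[idx]);
        }
      }
  }

  strengths.attr("dim") = IntegerVector::create(n_modes, nw, R, R);
  pvals.attr("dim") = IntegerVector::create(n_modes, nw, R, R);
  return List::create(_["strengths"] = strengths, _["pvals"] = pvals,
                      _["nulls"] = nulls);
}
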