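#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 after normalisation.
static void iir1(const double* b, const double* a, int nb, int na,
                 const double* x, double* y, int n) {
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = (nb > 0 ? b[0] * xi : 0.0) + (nz > 0 ? z[0] : 0.0);
    for (int j = 1; j <= nz; ++j) {
      double zj = (j < nz) ? z[j] : 0.0;
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      z[j - 1] = zj + bj * xi - aj * yi;
    }
    y[i] = yi;
  }
}

// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size();
  NumericVector y(n);
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (size_t j = 0; j < bb.size(); ++j) bb[j] /= aa[0];
  for (size_t j = 0; j < aa.size(); ++j) aa[j] /= aa[0];
  iir1(bb.data(), aa.data(), bb.size(), aa.size(), REAL(x), REAL(y), n);
  return y;
}

// Zero-phase filtering of each matrix column with odd-reflection edge padding
// (pad length 3 * (ncoef - 1), as is conventional for forward-backward IIR).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  int n = X.nrow(), nc = X.ncol();
  int nf = std::max(b.size(), a.size());
  int pad = 3 * (nf - 1);
  if (n <= pad) stop("signal too short for zero-phase filtering");
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  for (size_t j = 0; j < bb.size(); ++j) bb[j] /= aa[0];
  for (size_t j = 0; j < aa.size(); ++j) aa[j] /= aa[0];
  NumericMatrix Y(n, nc);
  int m = n + 2 * pad;
  std::vector<double> ext(m), tmp(m);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, 0) + (size_t)c * n;
    for (int i = 0; i < pad; ++i) ext[i] = 2.0 * x[0] - x[pad - i];
    for (int i = 0; i < n; ++i) ext[pad + i] = x[i];
    for (int i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
    iir1(bb.data(), aa.data(), bb.size(), aa.size(), ext.data(), tmp.data(), m);
    std::reverse(tmp.begin(), tmp.end());
    iir1(bb.data(), aa.data(), bb.size(), aa.size(), tmp.data(), ext.data(), m);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) Y(i, c) = ext[pad + i];
  }
  return Y;
}

// --- periodized orthogonal DWT ----------------------------------------------

// One analysis step: y_low[i] = sum_k lo[k] x[(2i+k) mod n], same for high.
static void dwt_step(const std::vector<double>& x,
                     const double* lo, const double* hi, int nf,
                     std::vector<double>& a, std::vector<double>& d) {
  int n = x.size(), nh = n / 2;
  a.assign(nh, 0.0); d.assign(nh, 0.0);
  for (int i = 0; i < nh; ++i) {
    double sa = 0.0, sd = 0.0;
    int base = 2 * i;
    for (int k = 0; k < nf; ++k) {
      double xv = x[(base + k) % n];
      sa += lo[k] * xv;
      sd += hi[k] * xv;
    }
    a[i] = sa; d[i] = sd;
  }
}

// Adjoint (= inverse, filters orthonormal) of the analysis step.
static void idwt_step(const std::vector<double>& a, const std::vector<double>& d,
                      const double* lo, const double* hi, int nf,
                      std::vector<double>& x) {
  int nh = a.size(), n = 2 * nh;
  x.assign(n, 0.0);
  for (int i = 0; i < nh; ++i) {
    int base = 2 * i;
    for (int k = 0; k < nf; ++k) {
      int idx = (base + k) % n;
      x[idx] += lo[k] * a[i] + hi[k] * d[i];
    }
  }
}

// Decompose each column to `levels` levels and reconstruct, per column, the
// contribution of every detail level D1..DL and the final approximation AL.
// Returns a list of L+1 matrices, each the size of X: D1, D2, ..., DL, AL.
// [[Rcpp::export]]
List cpp_dwt_band_reconstruct(NumericMatrix X, NumericVector lo, NumericVector hi,
                              int levels) {
  int n = X.nrow(), nc = X.ncol(), nf = lo.size();
  if (n % (1 << levels) != 0)
    stop("signal length must be divisible by 2^levels");
  List out(levels + 1);
  std::vector<NumericMatrix> mats;
  for (int l = 0; l <= levels; ++l) mats.push_back(NumericMatrix(n, nc));

  std::vector<double> cur, a, d, rec, zero;
  for (int c = 0; c < nc; ++c) {
    // analysis: keep all detail vectors
    std::vector<std::vector<double> > details(levels);
    cur.assign(X.column(c).begin(), X.column(c).end());
    for (int l = 0; l < levels; ++l) {
      dwt_step(cur, REAL(lo), REAL(hi), nf, a, d);
      details[l] = d;
      cur = a;
    }
    std::vector<double> approx = cur;
    // reconstruct each band independently
    for (int l = 0; l <= levels; ++l) {
      // start at depth `start` with either detail (l<levels) or approx
      int start = (l < levels) ? l : levels - 1;
      if (l < levels) {
        zero.assign(details[l].size(), 0.0);
        idwt_step(zero, details[l], REAL(lo), REAL(hi), nf, rec);
      } else {
        zero.assign(approx.size(), 0.0);
        idwt_step(approx, zero, REAL(lo), REAL(hi), nf, rec);
      }
      for (int up = start - 1; up >= 0; --up) {
        zero.assign(rec.size(), 0.0);
        std::vector<double> nxt;
        idwt_step(rec, zero, REAL(lo), REAL(hi), nf, nxt);
        rec = nxt;
      }
      NumericMatrix& M = mats[l];
      for (int i = 0; i < n; ++i) M(i, c) = rec[i];
    }
  }
  for (int l = 0; l <= levels; ++l) out[l] = mats[l];
  return out;
}

// --- sample entropy template counts -----------------------------------------

// Counts of template pairs (i < j, i,j <= n - m - 1 zero-based) whose
// Chebyshev distance is <= r, at template lengths m and m + 1; self-matches
// excluded by construction.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of templates of length m that also extend to m+1
  double bm = 0.0, bm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > dmax) dmax = dd;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      bm += 1.0;
      double dd = std::fabs(x[i + m] - x[j + m]);
      if (dmax <= r && dd <= r) bm1 += 1.0;
    }
  }
  return NumericVector::create(bm, bm1);
}

// --- polyphase windowed-sinc resampling -------------------------------------

// Rational/irrational-rate resampling of each column by interpolation with a
// Kaiser-windowed sinc anti-imaging kernel (cutoff at the output Nyquist;
// the caller guarantees prior band-limiting). `half` taps on each side.
// [[Rcpp::export]]
NumericMatrix cpp_resample(NumericMatrix X, double fs_in, double fs_out,
                           int half) {
  int n = X.nrow(), nc = X.ncol();
  int m = (int)std::lround((double)n * fs_out / fs_in);
  double ratio = fs_in / fs_out;
  double nu = 0.5 * std::min(fs_out, fs_in) / fs_in * 0.92;  // cycles/input sample
  NumericMatrix Y(m, nc);
  std::vector<double> taps(2 * half);
  const double beta = 8.0;
  // Kaiser window I0
  auto bessel_i0 = [](double x) {
    double s = 1.0, t = 1.0;
    for (int k = 1; k < 32; ++k) { t *= (x / (2.0 * k)) * (x / (2.0 * k)); s += t; }
    return s;
  };
  double i0b = bessel_i0(beta);
  for (int i = 0; i < m; ++i) {
    double pos = i * ratio;
    int n0 = (int)std::floor(pos);
    double frac = pos - n0;
    double wsum = 0.0;
    for (int k = 0; k < 2 * half; ++k) {
      double t = (k - half + 1) - frac;  // offset of tap sample from pos
      double sinc = (std::fabs(t) < 1e-12) ? 1.0
        : std::sin(2.0 * M_PI * nu * t) / (2.0 * M_PI * nu * t);
      double u = t / half;
      double w = (std::fabs(u) <= 1.0)
        ? bessel_i0(beta * std::sqrt(1.0 - u * u)) / i0b : 0.0;
      taps[k] = sinc * w;
      wsum += taps[k];
    }
    for (int k = 0; k < 2 * half; ++k) taps[k] /= wsum;  // exact DC gain
    for (int c = 0; c < nc; ++c) {
      const double* x = &X(0, 0) + (size_t)c * n;
      double acc = 0.0;
      for (int k = 0; k < 2 * half; ++k) {
        int idx = n0 + k - half + 1;
        if (idx < 0) idx = 0;
        if (idx >= n) idx = n - 1;
        acc += taps[k] * x[idx];
      }
      Y(i, c) = acc;
    }
  }
  return Y;
}

// --- batch helpers for the closed-loop simulator ----------------------------

// Per-band second moments from the analysis DWT alone: for an orthonormal
// periodized transform the reconstruction of each band has sum of squares
// equal to that of its coefficients (Parseval), detail reconstructions have
// zero mean, and the approximation carries the signal mean. Returns a
// (levels+2) x ncol matrix: rows 0..levels-1 = sum c^2 of D1..DL, row
// levels = sum c^2 of AL, row levels+1 = column mean of X.
// [[Rcpp::export]]
NumericMatrix cpp_dwt_band_moments(NumericMatrix X, NumericVector lo,
                                   NumericVector hi, int levels) {
  int n = X.nrow(), nc = X.ncol(), nf = lo.size();
  if (n % (1 << levels) != 0) stop("signal length must be divisible by 2^levels");
  NumericMatrix M(levels + 2, nc);
  std::vector<double> cur, a, d;
  for (int c = 0; c < nc; ++c) {
    cur.assign(X.column(c).begin(), X.column(c).end());
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += cur[i];
    M(levels + 1, c) = mean / n;
    for (int l = 0; l < levels; ++l) {
      dwt_step(cur, REAL(lo), REAL(hi), nf, a, d);
      double ss = 0.0;
      for (size_t i = 0; i < d.size(); ++i) ss += d[i] * d[i];
      M(l, c) = ss;
      cur = a;
    }
    double ss = 0.0;
    for (size_t i = 0; i < cur.size(); ++i) ss += cur[i] * cur[i];
    M(levels, c) = ss;
  }
  return M;
}

// Mix band-limited noise for the signal generator: for each channel, filter
// its white-noise column through every band's IIR filter, normalise the
// component to unit sd, scale by amps(band, channel) and sum.
// [[Rcpp::export]]
NumericMatrix cpp_mix_bands(NumericMatrix W, List b_list, List a_list,
                            NumericMatrix amps) {
  int n = W.nrow(), nc = W.ncol(), nb = b_list.size();
  NumericMatrix Y(n, nc);
  std::vector<double> tmp(n);
  for (int bi = 0; bi < nb; ++bi) {
    NumericVector b = b_list[bi], a = a_list[bi];
    std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
    for (size_t j = 0; j < bb.size(); ++j) bb[j] /= aa[0];
    for (size_t j = 0; j < aa.size(); ++j) aa[j] /= aa[0];
    for (int c = 0; c < nc; ++c) {
      if (amps(bi, c) == 0.0) continue;
      iir1(bb.data(), aa.data(), bb.size(), aa.size(), &W(0, 0) + (size_t)c * n,
           tmp.data(), n);
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < n; ++i) { s += tmp[i]; ss += tmp[i] * tmp[i]; }
      double sdv = std::sqrt((ss - s * s / n) / (n - 1));
      double g = amps(bi, c) / (sdv > 0 ? sdv : 1.0);
      for (int i = 0; i < n; ++i) Y(i, c) += g * tmp[i];
    }
  }
  return Y;
}
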