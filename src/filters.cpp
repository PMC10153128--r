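#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One forward pass of a direct-form II transposed IIR filter, in place.
// b and a must already be padded to equal length and normalised (a[0] == 1).
static void filt_pass(const double* b, const double* a, int nz,
                      double* x, R_xlen_t n) {
  if (nz == 2) {  // biquad fast path
    const double b0 = b[0], b1 = b[1], b2 = b[2], a1 = a[1], a2 = a[2];
    double z1 = 0.0, z2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi + z2 - a1 * yi;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
    return;
  }
  std::vector<double> z(nz, 0.0);
  double* zp = z.data();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz > 0 ? zp[0] : 0.0);
    for (int j = 1; j < nz; ++j)
      zp[j - 1] = b[j] * xi + zp[j] - a[j] * yi;
    if (nz > 0)
      zp[nz - 1] = b[nz] * xi - a[nz] * yi;
    x[i] = yi;
  }
}

static void prep_coef(NumericVector b, NumericVector a,
                      std::vector<double>& bb, std::vector<double>& aa) {
  const int m = std::max(b.size(), a.size());
  bb.assign(m, 0.0);
  aa.assign(m, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] != 1.0) {
    for (int i = 0; i < m; ++i) bb[i] /= aa[0];
    for (int i = m - 1; i >= 0; --i) aa[i] /= aa[0];
  }
}

// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericMatrix x, NumericVector b, NumericVector a) {
  std::vector<double> bb, aa;
  prep_coef(b, a, bb, aa);
  const int nz = (int)bb.size() - 1;
  const R_xlen_t n = x.nrow();
  NumericMatrix out(clone(x));
  for (int c = 0; c < out.ncol(); ++c) {
    double* col = &out(0, c);
    filt_pass(bb.data(), aa.data(), nz, col, n);
    std::reverse(col, col + n);
    filt_pass(bb.data(), aa.data(), nz, col, n);
    std::reverse(col, col + n);
  }
  return out;
}

// Cascade of biquad sections (second-order sections), zero-phase.
// sos: k x 6 matrix, rows (b0 b1 b2 a0 a1 a2).
// [[Rcpp::export(name = ".filtfilt_sos_mat")]]
NumericMatrix filtfilt_sos_mat(NumericMatrix x, NumericMatrix sos) {
  const R_xlen_t n = x.nrow();
  NumericMatrix out(clone(x));
  const int ns = sos.nrow();
  std::vector<std::vector<double> > BB(ns), AA(ns);
  for (int s = 0; s < ns; ++s) {
    NumericVector bs = NumericVector::create(sos(s, 0), sos(s, 1), sos(s, 2));
    NumericVector as = NumericVector::create(sos(s, 3), sos(s, 4), sos(s, 5));
    prep_coef(bs, as, BB[s], AA[s]);
  }
  for (int c = 0; c < out.ncol(); ++c) {
    double* col = &out(0, c);
    for (int pass = 0; pass < 2; ++pass) {
      for (int s = 0; s < ns; ++s)
        filt_pass(BB[s].data(), AA[s].data(), 2, col, n);
      std::reverse(col, col + n);
    }
  }
  return out;
}

// FIR smoothing kernel evaluated only at decimated output points.
// x: samples x channels, kern: odd-length normalised kernel, factor: decimation.
// Output sample j (1-based) corresponds to input sample (j-1)*factor + 1.
// Edges are zero-padded.
// [[Rcpp::export(name = ".smooth_decimate_mat")]]
NumericMatrix smooth_decimate_mat(NumericMatrix x, NumericVector kern, int factor,
                                  bool rectify = false) {
  const R_xlen_t n = x.nrow();
  const int nk = kern.size();
  const int half = nk / 2;
  const R_xlen_t nout = (n - 1) / factor + 1;
  std::vector<double> kk(kern.begin(), kern.end());
  const double* kp = kk.data();
  NumericMatrix out((int)nout, x.ncol());
  for (int c = 0; c < x.ncol(); ++c) {
    const double* col = &x(0, c);
    double* oc = &out(0, c);
    for (R_xlen_t j = 0; j < nout; ++j) {
      const R_xlen_t center = j * factor;
      const int l0 = (int)std::max((R_xlen_t)0, half - center);
      const int l1 = (int)std::min((R_xlen_t)nk, n - center + half);
      const double* xp = col + center - half;
      double acc = 0.0;
      if (rectify)
        for (int l = l0; l < l1; ++l)
          acc += kp[l] * std::fabs(xp[l]);
      else
        for (int l = l0; l < l1; ++l)
          acc += kp[l] * xp[l];
      oc[j] = acc;
    }
  }
  return out;
}

// In-place accumulation of values at (1-based) indices, duplicate-safe.
// [[Rcpp::export(name = ".add_at")]]
NumericVector add_at(NumericVector x, IntegerVector idx, NumericVector val) {
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    const R_xlen_t j = idx[i] - 1;
    if (j >= 0 && j < x.size()) x[j] += val[i];
  }
  return x;
}

// Fast deterministic Gaussian noise added in place (xorshift128+ with
// Box-Muller); keeps the large background fills out of R's RNG stream,
// seeded explicitly by the caller.
// [[Rcpp::export(name = ".add_white_noise")]]
NumericMatrix add_white_noise(NumericMatrix x, double sd, double seed) {
  uint64_t s0 = (uint64_t)seed * 2685821657736338717ULL + 1ULL;
  uint64_t s1 = s0 ^ 0x9E3779B97F4A7C15ULL;
  // warm up
  for (int i = 0; i < 16; ++i) {
    uint64_t t = s0 ^ (s0 << 23);
    s0 = s1;
    s1 = t ^ s1 ^ (t >> 18) ^ (s1 >> 5);
  }
  const R_xlen_t n = x.size();
  double* p = REAL(x);
  R_xlen_t i = 0;
  while (i < n) {
    uint64_t t = s0 ^ (s0 << 23);
    s0 = s1;
    s1 = t ^ s1 ^ (t >> 18) ^ (s1 >> 5);
    uint64_t r1 = s0 + s1;
    t = s0 ^ (s0 << 23);
    s0 = s1;
    s1 = t ^ s1 ^ (t >> 18) ^ (s1 >> 5);
    uint64_t r2 = s0 + s1;
    double u1 = ((r1 >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    double u2 = ((r2 >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    double rad = std::sqrt(-2.0 * std::log(u1)) * sd;
    double ang = 6.283185307179586 * u2;
    p[i++] += rad * std::cos(ang);
    if (i < n) p[i++] += rad * std::sin(ang);
  }
  return x;
}
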