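// Per-object gray-level co-occurrence (Haralick) texture statistics.
//
// For each labelled region the channel intensities are quantized to
// `nlevels` equal-width bins between the region's own min and max, the
// symmetric co-occurrence matrix is accumulated at the given pixel distance
// for each of the four principal directions, and 13 classical statistics
// are computed per direction and averaged. Natural logarithms throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void haralick13(const std::vector<double>& P, int N, double* out) {
  // P is a normalized symmetric N x N co-occurrence matrix (column-major);
  // only its nonzero entries are visited (object GLCMs are sparse)
  std::vector<double> px(N, 0.0), psum(2 * N - 1, 0.0), pdiff(N, 0.0);
  std::vector<int> nzi, nzj;
  double asm_ = 0, contrast = 0, idm = 0, entropy = 0, mean = 0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      const double v = P[i + j * N];
      if (v <= 0) continue;
      nzi.push_back(i); nzj.push_back(j);
      px[i] += v;
      psum[i + j] += v;
      pdiff[std::abs(i - j)] += v;
      asm_ += v * v;
      contrast += (double)(i - j) * (i - j) * v;
      idm += v / (1.0 + (double)(i - j) * (i - j));
      entropy -= v * std::log(v);
    }
  for (int i = 0; i < N; ++i) mean += (i + 1.0) * px[i];
  double var = 0, hx = 0;
  for (int i = 0; i < N; ++i) {
    var += (i + 1.0 - mean) * (i + 1.0 - mean) * px[i];
    if (px[i] > 0) hx -= px[i] * std::log(px[i]);
  }
  double corr = 0;
  if (var > 1e-12) {
    double s = 0;
    for (size_t k = 0; k < nzi.size(); ++k)
      s += (nzi[k] + 1.0) * (nzj[k] + 1.0) * P[nzi[k] + nzj[k] * N];
    corr = (s - mean * mean) / var;  // symmetric: mu_x = mu_y, sd_x = sd_y
  }
  double sumavg = 0, sumvar = 0, sument = 0;
  for (int k = 0; k < 2 * N - 1; ++k) {
    const double v = psum[k];
    if (v <= 0) continue;
    sumavg += (k + 2.0) * v;
    sument -= v * std::log(v);
  }
  for (int k = 0; k < 2 * N - 1; ++k) {
    const double v = psum[k];
    if (v > 0) sumvar += (k + 2.0 - sumavg) * (k + 2.0 - sumavg) * v;
  }
  double dmean = 0, dvar = 0, dent = 0;
  for (int k = 0; k < N; ++k) dmean += k * pdiff[k];
  for (int k = 0; k < N; ++k) {
    const double v = pdiff[k];
    if (v <= 0) continue;
    dvar += (k - dmean) * (k - dmean) * v;
    dent -= v * std::log(v);
  }
  // information measures of correlation (restricted to nonzero marginals)
  double hxy1 = 0, hxy2 = 0;
  std::vector<int> nzpx;
  for (int i = 0; i < N; ++i) if (px[i] > 0) nzpx.push_back(i);
  for (size_t a = 0; a < nzpx.size(); ++a)
    for (size_t b = 0; b < nzpx.size(); ++b) {
      const double pp = px[nzpx[a]] * px[nzpx[b]];
      const double lpp = std::log(pp);
      hxy2 -= pp * lpp;
      const double pij = P[nzpx[a] + nzpx[b] * N];
      if (pij > 0) hxy1 -= pij * lpp;
    }
  double imc1 = 0, imc2 = 0;
  if (hx > 1e-12) imc1 = (entropy - hxy1) / hx;
  const double e2 = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  if (e2 > 0) imc2 = std::sqrt(e2);

  out[0] = asm_;     out[1] = contrast; out[2] = corr;   out[3] = var;
  out[4] = idm;      out[5] = sumavg;   out[6] = sumvar; out[7] = sument;
  out[8] = entropy;  out[9] = dvar;     out[10] = dent;  out[11] = imc1;
  out[12] = imc2;
}

// [[Rcpp::export(name = ".glcm_features_cpp")]]
NumericMatrix glcm_features_cpp(NumericMatrix img, IntegerMatrix labels,
                                int nlabels, int nlevels, int dist) {
  const int nr = img.nrow(), nc = img.ncol();
  if (labels.nrow() != nr || labels.ncol() != nc)
    stop("label mask shape does not match image shape");
  if (nlabels < 1) return NumericMatrix(0, 13);

  // per-label quantization range
  std::vector<double> lo(nlabels, R_PosInf), hi(nlabels, R_NegInf);
  for (int i = 0; i < nr * nc; ++i) {
    const int l = labels[i];
    if (l > 0 && l <= nlabels) {
      if (img[i] < lo[l - 1]) lo[l - 1] = img[i];
      if (img[i] > hi[l - 1]) hi[l - 1] = img[i];
    }
  }
  std::vector<int> q(nr * nc, 0);
  for (int i = 0; i < nr * nc; ++i) {
    const int l = labels[i];
    if (l > 0 && l <= nlabels) {
      const double rng = hi[l - 1] - lo[l - 1];
      int lev = rng > 0 ?
        (int)std::floor((img[i] - lo[l - 1]) / rng * nlevels) : 0;
      if (lev >= nlevels) lev = nlevels - 1;
      q[i] = lev;  // 0-based level
    }
  }

  const int N = nlevels;
  const int drs[4] = {0, dist, dist, dist};
  const int dcs[4] = {dist, 0, dist, -dist};

  NumericMatrix out(nlabels, 13);
  std::vector<int> ndir(nlabels, 0);
  std::vector<double> G((size_t)nlabels * N * N);
  std::vector<double> tot(nlabels);

  for (int d = 0; d < 4; ++d) {
    std::fill(G.begin(), G.end(), 0.0);
    std::fill(tot.begin(), tot.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      const int c2 = c + dcs[d];
      if (c2 < 0 || c2 >= nc) continue;
      for (int r = 0; r < nr; ++r) {
        const int r2 = r + drs[d];
        if (r2 < 0 || r2 >= nr) continue;
        const int i = r + c * nr, j = r2 + c2 * nr;
        const int l = labels[i];
        if (l > 0 && l <= nlabels && labels[j] == l) {
          double* g = &G[(size_t)(l - 1) * N * N];
          g[q[i] + q[j] * N] += 1.0;
          g[q[j] + q[i] * N] += 1.0;
          tot[l - 1] += 2.0;
        }
      }
    }
    for (int l = 0; l < nlabels; ++l) {
      if (tot[l] <= 0) continue;
      std::vector<double> P(N * N);
      const double* g = &G[(size_t)l * N * N];
      for (int k = 0; k < N * N; ++k) P[k] = g[k] / tot[l];
      double stats[13];
      haralick13(P, N, stats);
      for (int s = 0; s < 13; ++s) out(l, s) += stats[s];
      ndir[l] += 1;
    }
  }
  for (int l = 0; l < nlabels; ++l) {
    if (ndir[l] > 0) {
      for (int s = 0; s < 13; ++s) out(l, s) /= ndir[l];
    } else {
      for (int s = 0; s < 13; ++s) out(l, s) = NA_REAL;
    }
  }
  return out;
}
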